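tissue	system
testis	reproductive
epididymis	reproductive
seminal vesicle	reproductive
prostate	reproductive
ovary	reproductive
fallopian tube	reproductive
endometrium	reproductive
cervix	reproductive
placenta	reproductive
breast	reproductive
spleen	immune
lymph node	immune
tonsil	immune
thymus	immune
bone marrow	immune
appendix	immune
cerebral cortex	nervous
cerebellum	nervous
hippocampus	nervous
caudate	nervous
hypothalamus	nervous
spinal cord	nervous
peripheral nerve	nervous
retina	nervous
esophagus	other
stomach	other
duodenum	other
small intestine	other
colon	other
rectum	other
liver	other
gallbladder	other
pancreas	other
kidney	other
urinary bladder	other
lung	other
bronchus	other
nasopharynx	other
skin	other
adipose tissue	other
smooth muscle	other
skeletal muscle	other
heart muscle	other
thyroid gland	other
parathyroid gland	other
adrenal gland	other
salivary gland	other
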
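# Permethylated benzyl glycoside mass arithmetic and glycome normalization.

printed_glycome <- data.frame(
  label  = c("T", "sialyl-T", "STn", "core 3", "core 2 Hex1HexNAc2",
             "core 2 Hex2HexNAc2", "core 2 fucosylated",
             "core 2 sialylated", "core 2 Hex3HexNAc3", "di-sialyl-T"),
  hex    = c(1, 1, 0, 0, 1, 2, 2, 2, 3, 1),
  hexnac = c(1, 1, 1, 2, 2, 2, 2, 2, 3, 1),
  dhex   = c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0),
  neuac  = c(0, 1, 1, 0, 0, 0, 0, 1, 0, 2),
  mz     = c(572.31, 933.48, 729.4, 613.33, 817.43, 1021.53, 1195.62,
             1382.71, 1470.76, 1294.7),
  digits = c(2, 2, 1, 2, 2, 2, 2, 2, 2, 1),
  stringsAsFactors = FALSE
)

test_that("printed O-glycome m/z values are reproduced at printed precision", {
  for (i in seq_len(nrow(printed_glycome))) {
    row <- printed_glycome[i, ]
    comp <- glycan_composition(row$hex, row$hexnac, row$dhex, row$neuac)
    expect_equal(round(glycan_mz(comp), row$digits), row$mz,
                 info = row$label)
  }
})

test_that("neutral masses agree with the element-level oracle", {
  expect_equal(permethylated_benzyl_mass(glycan_composition(hex = 1)),
               326.1729, tolerance = 1e-4)
  expect_equal(permethylated_benzyl_mass(glycan_composition(1, 1)),
               571.2993, tolerance = 1e-4)
  set.seed(11)
  for (k in 1:25) {
    counts <- list(Hex = sample(0:4, 1), HexNAc = sample(0:4, 1),
                   dHex = sample(0:2, 1), NeuAc = sample(0:2, 1))
    if (sum(unlist(counts)) == 0) counts$Hex <- 1
    comp <- glycan_composition(counts$Hex, counts$HexNAc,
                               counts$dHex, counts$NeuAc)
    expect_equal(permethylated_benzyl_mass(comp),
                 oracle_glycan_mass(counts), tolerance = 1e-5)
  }
})

test_that("adding one residue adds its fixed permethylated increment", {
  increments <- c(Hex = 204.0998, HexNAc = 245.1263,
                  dHex = 174.0892, NeuAc = 361.1737)
  set.seed(7)
  for (k in 1:20) {
    base <- c(Hex = sample(0:3, 1), HexNAc = sample(1:3, 1),
              dHex = sample(0:2, 1), NeuAc = sample(0:2, 1))
    cls <- sample(names(increments), 1)
    grown <- base
    grown[cls] <- grown[cls] + 1
    d <- permethylated_benzyl_mass(as_comp <- do.call(
      glycan_composition, as.list(unname(grown)))) -
      permethylated_benzyl_mass(do.call(
        glycan_composition, as.list(unname(base))))
    expect_equal(d, unname(increments[cls]), tolerance = 1e-4)
  }
})

test_that("multiply charged and free-reducing-end variants behave", {
  comp <- glycan_composition(2, 2)
  expect_equal(round(glycan_mz(comp, charge = 2), 2), 511.27)
  expect_lt(glycan_mz(comp, benzyl = FALSE), glycan_mz(comp))
  expect_error(glycan_mz(comp, charge = 0), "charge")
  expect_error(glycan_composition(0, 0), "at least one residue")
  expect_error(glycan_composition(-1, 2), "non-negative")
})

test_that("assign_composition inverts mz and ranks by error", {
  hit <- assign_composition(933.48, max_per_class = 4, tolerance = 0.05)
  expect_equal(unlist(hit[1, c("Hex", "HexNAc", "dHex", "NeuAc")]),
               c(Hex = 1, HexNAc = 1, dHex = 0, NeuAc = 1))
  hit <- assign_composition(1470.76, max_per_class = 6, tolerance = 0.05)
  expect_equal(unlist(hit[1, c("Hex", "HexNAc", "dHex", "NeuAc")]),
               c(Hex = 3, HexNAc = 3, dHex = 0, NeuAc = 0))
  expect_equal(nrow(assign_composition(100.0, tolerance = 0.01)), 0L)
  # exact inverse property over the whole bounded composition space
  grid <- expand.grid(h = 0:2, n = 0:2, f = 0:1, s = 0:1)
  grid <- grid[rowSums(grid) > 0, ]
  for (i in seq_len(nrow(grid))) {
    comp <- glycan_composition(grid$h[i], grid$n[i], grid$f[i], grid$s[i])
    top <- assign_composition(glycan_mz(comp), max_per_class = 3,
                              tolerance = 0.01)[1, ]
    expect_equal(unname(unlist(top[c("Hex", "HexNAc", "dHex", "NeuAc")])),
                 unname(unclass(comp)))
  }
})

test_that("glycome normalization sums to one and is scale-invariant", {
  p <- normalize_glycome(data.frame(intensity = c(1, 2, 7)))
  expect_equal(p$relative_abundance, c(0.1, 0.2, 0.7))
  set.seed(3)
  ints <- runif(50, 0, 1e6)
  p1 <- normalize_glycome(data.frame(intensity = ints))
  p2 <- normalize_glycome(data.frame(intensity = ints * 37.5))
  expect_equal(sum(p1$relative_abundance), 1, tolerance = 1e-9)
  expect_equal(p1$relative_abundance, p2$relative_abundance)
  expect_error(normalize_glycome(data.frame(intensity = c(0, 0))),
               "all intensities are zero")
  expect_error(normalize_glycome(data.frame(intensity = c(-1, 2))), ">= 0")
})

test_that("annotate_glycome labels peaks from a composition library", {
  peaks <- data.frame(mz = c(572.31, 933.48, 50.0),
                      intensity = c(30, 10, 5))
  lib <- data.frame(label = c("T antigen", "sialyl-T"),
                    Hex = c(1, 1), HexNAc = c(1, 1),
                    dHex = c(0, 0), NeuAc = c(0, 1),
                    stringsAsFactors = FALSE)
  prof <- annotate_glycome(peaks, tolerance = 0.05, library = lib)
  expect_equal(nrow(prof), 2L)  # 50.0 unassignable
  expect_equal(prof$label, c("T antigen", "sialyl-T"))
  expect_equal(prof$relative_abundance, c(0.75, 0.25))
})
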
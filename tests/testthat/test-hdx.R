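test_that("deuterium fraction follows the mixing-volume rule", {
  expect_equal(round(deuterium_fraction(15, 55), 3), 0.786)
  expect_equal(deuterium_fraction(7, 7), 0.5)
  expect_error(deuterium_fraction(0, 55), "> 0")
})

test_that("exchangeable-amide counting drops the first residue and prolines", {
  expect_identical(count_exchangeable("PGPLG"), 3L)
  expect_identical(count_exchangeable("AA"), 1L)
  expect_identical(count_exchangeable("APPP"), 0L)
  expect_identical(count_exchangeable("PAP", convention = "first_two"), 0L)
  expect_error(count_exchangeable(""), "empty")
})

test_that("the uptake forward model saturates and integrates per residue", {
  cond <- labeling_conditions()
  pep <- hdx_peptide(10L, 14L, "GAVLK")   # 4 exchangeable
  expect_equal(peptide_uptake_model(pep, rep(0.5, 5), cond, 0), 0)
  expect_equal(peptide_uptake_model(pep, rep(Inf, 5), cond, 1),
               4 * deuterium_fraction(15, 55), tolerance = 1e-12)
  # single exchangeable residue closed form
  pep1 <- hdx_peptide(1L, 2L, "GA")
  expect_equal(peptide_uptake_model(pep1, c(0, 0.1), cond, 10),
               deuterium_fraction(15, 55) * (1 - exp(-1)), tolerance = 1e-12)
  expect_error(peptide_uptake_model(pep, c(-1, 1, 1, 1, 1), cond, 1),
               "negative")
  # monotone in t
  up <- peptide_uptake_model(pep, c(0, 0.01, 0.2, 1, 5), cond,
                             c(0.16, 1, 10, 30, 60, 120, 180))
  expect_true(all(diff(up) >= 0))
})

test_that("uptake is additive over a partition of exchangeable residues", {
  cond <- labeling_conditions()
  # left covers amides 2-5, right (K first, uncounted) covers 6-9:
  # together they partition the whole peptide's amides 2-9
  whole <- hdx_peptide(1L, 9L, "GAVLKSTNQ")
  left <- hdx_peptide(1L, 5L, "GAVLK")
  right <- hdx_peptide(5L, 9L, "KSTNQ")
  k <- c(0, 0.02, 0.1, 0.5, 1, 0.3, 0.05, 2, 0.7)
  t <- c(1, 10, 60)
  u_whole <- peptide_uptake_model(whole, k, cond, t)
  u_parts <- peptide_uptake_model(left, k[1:5], cond, t) +
    peptide_uptake_model(right, k[5:9], cond, t)
  expect_equal(u_whole, u_parts, tolerance = 1e-12)
})

test_that("relative fractional uptake normalizes by the theoretical maximum", {
  cond <- labeling_conditions()
  pep <- hdx_peptide(1L, 8L, "GAVLKSTN")  # 7 exchangeable
  dmax <- 7 * cond$d_fraction
  expect_equal(relative_fractional_uptake(dmax, pep, cond), 1)
  expect_equal(relative_fractional_uptake(0, pep, cond), 0)
  expect_equal(relative_fractional_uptake(2.75, pep, cond),
               2.75 / (7 * deuterium_fraction(15, 55)), tolerance = 1e-12)
  expect_true(isTRUE(attr(
    relative_fractional_uptake(1.2 * dmax, pep, cond), "clipped")))
  expect_error(relative_fractional_uptake(1, hdx_peptide(1L, 2L, "GP"), cond),
               "no exchangeable")
})

test_that("identical states produce no significant peptides", {
  prot <- make_protomer(80L, seed = 4L)
  cond <- labeling_conditions()
  rates <- default_hdx_truth(prot$sequence, slow_region = integer(0),
                             seed = 5L)
  pmap <- make_peptide_map(prot$sequence, seed = 6L)
  tabs <- make_hdx_tables(list(A = rates$A, B = rates$A), pmap, cond,
                          noise_sd = 0.05, seed = 7L)
  tabs$B$data$uptake_Da <- tabs$A$data$uptake_Da  # byte-identical values
  cmp <- compare_states(tabs$A, tabs$B, cond)
  expect_identical(sum(cmp$peptides$significant), 0L)
  expect_true(all(cmp$peptides$class == "none"))
  expect_true(all(cmp$residues$class == "none", na.rm = TRUE))
  expect_true(all(cmp$dRFU == 0))
})

test_that("a moderate significant shift is classed minor by thresholds", {
  cond <- labeling_conditions(time_points = c(1, 10, 60))
  seqs <- "GAVLKSTNQY"                      # 9 exchangeable
  pep <- data.frame(start = 1L, end = 10L, sequence = seqs)
  n_ex <- count_exchangeable(seqs)
  base <- n_ex * cond$d_fraction * 0.5
  shift <- 0.07 * n_ex * cond$d_fraction    # dRFU exactly 0.07
  mk <- function(level) {
    rows <- expand.grid(time_min = cond$time_points, replicate = 1:3)
    set.seed(31)
    uptake_table(data.frame(start = 1L, end = 10L, sequence = seqs,
                            time_min = rows$time_min,
                            replicate = rows$replicate,
                            uptake_Da = level + rnorm(nrow(rows), 0, 0.005)),
                 state = "x")
  }
  a <- mk(base)
  set.seed(77)
  b <- mk(base)
  b$data$uptake_Da <- b$data$uptake_Da - shift + rnorm(9, 0, 0.005)
  cmp <- compare_states(a, b, cond)
  expect_true(cmp$peptides$significant[1L])
  expect_identical(cmp$peptides$class[1L], "minor")
})

test_that("swapping state labels negates dRFU and preserves p-values", {
  prot <- make_protomer(70L, seed = 9L)
  cond <- labeling_conditions()
  rates <- default_hdx_truth(prot$sequence, slow_region = 20:30, seed = 10L)
  pmap <- make_peptide_map(prot$sequence, seed = 11L)
  tabs <- make_hdx_tables(rates, pmap, cond, noise_sd = 0.05, seed = 12L)
  c1 <- compare_states(tabs$A, tabs$B, cond)
  c2 <- compare_states(tabs$B, tabs$A, cond)
  expect_equal(c1$dRFU, -c2$dRFU, tolerance = 1e-10)
  expect_equal(c1$peptides$p_magnitude, c2$peptides$p_magnitude,
               tolerance = 1e-10)
  expect_equal(c1$peptides$p_kinetics, c2$peptides$p_kinetics,
               tolerance = 1e-10)
})

test_that("comparison rejects mismatched maps and missing replicates", {
  prot <- make_protomer(70L, seed = 13L)
  cond <- labeling_conditions()
  rates <- default_hdx_truth(prot$sequence, seed = 14L)
  pmap <- make_peptide_map(prot$sequence, seed = 15L)
  tabs <- make_hdx_tables(rates, pmap, cond, seed = 16L)
  short <- uptake_table(tabs$B$data[tabs$B$data$start > 5, ], "B")
  expect_error(compare_states(tabs$A, short, cond), "maps differ")
  single <- uptake_table(tabs$B$data[tabs$B$data$replicate == 1L, ], "B")
  expect_error(compare_states(tabs$A, single, cond), "replicates")
})

test_that("uptake tables round-trip through the tabular dialect", {
  prot <- make_protomer(70L, seed = 17L)
  pmap <- make_peptide_map(prot$sequence, seed = 18L)
  tabs <- make_hdx_tables(default_hdx_truth(prot$sequence, seed = 19L),
                          pmap, labeling_conditions(), seed = 20L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_uptake_table(tabs$A, f)
  back <- read_uptake_table(f, state = "A")
  expect_equal(back$data$uptake_Da, tabs$A$data$uptake_Da, tolerance = 1e-10)
  expect_identical(back$data$sequence, tabs$A$data$sequence)
})
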
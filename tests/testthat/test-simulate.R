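test_that("ground truth is deterministic with the planted-count contract", {
  gt1 <- generate_ground_truth(n_proteins = 100, prop_diff = 0.1,
                               seed = 42)
  gt2 <- generate_ground_truth(n_proteins = 100, prop_diff = 0.1,
                               seed = 42)
  expect_identical(gt1, gt2)
  gt3 <- generate_ground_truth(n_proteins = 100, prop_diff = 0.1,
                               seed = 43)
  expect_false(identical(gt1$fold, gt3$fold))

  # exactly floor(n * prop_diff) non-null per drawn mutant
  for (s in c("ubp8", "gcn5")) {
    expect_equal(sum(gt1$fold[, s] != 1), 10L)
  }
  expect_true(all(gt1$fold[, "WT"] == 1))
  # double mutant follows the product rule
  expect_equal(gt1$fold[, "ubp8_gcn5"],
               gt1$fold[, "ubp8"] * gt1$fold[, "gcn5"])
  # labels consistent with fold factors
  expect_true(all((gt1$fold > 1) == (gt1$labels == "up_in_mutant")))
  expect_true(all((gt1$fold < 1) == (gt1$labels == "down_in_mutant")))
  expect_true(all(gt1$proteins$lambda > 0))

  null_gt <- generate_ground_truth(n_proteins = 100, prop_diff = 0,
                                   seed = 1)
  expect_true(all(null_gt$fold == 1))
  expect_true(all(null_gt$labels == "null"))

  expect_error(generate_ground_truth(fold_range = c(0.8, 2)))
  expect_error(generate_ground_truth(prop_diff = 1.2))
})

test_that("simulated runs are deterministic and follow the design", {
  gt <- generate_ground_truth(n_proteins = 80, seed = 1)
  design <- sim_design(bio_reps = 2, tech_reps = 2, seed = 2)
  r1 <- simulate_runs(gt, design)
  r2 <- simulate_runs(gt, design)
  expect_identical(r1, r2)
  expect_length(r1, 16L)  # 4 strains x 2 preparations x 2 technical
  coords <- t(vapply(r1, function(r) {
    c(r$strain, r$bio_rep, r$tech_rep)
  }, character(3)))
  expect_equal(anyDuplicated(coords), 0L)
  # included records are identifications: spc > 0, unique_peptides >= 1
  for (r in r1) {
    expect_true(all(r$records$spc > 0))
    expect_true(all(r$records$unique_peptides >= 1))
  }
  expect_error(simulate_runs(gt, sim_design(strains = c("WT", "zzz"))),
               "zzz")
})

test_that("simulated counts average to lambda * fold at high abundance", {
  # law-of-large-numbers check: lambda = 100, no dropout, 200 proteins
  gt <- generate_ground_truth(n_proteins = 200, prop_diff = 0.5,
                              fold_range = c(2, 2),
                              baseline_meanlog = log(100),
                              baseline_sdlog = 0,
                              strains = c("WT", "mut"),
                              product_strain = NULL, seed = 10)
  design <- sim_design(strains = c("WT", "mut"), bio_reps = 2,
                       tech_reps = 2, dropout = FALSE, seed = 11)
  prof <- average_strain_profiles(align_lists(simulate_runs(gt, design)))
  aspc <- prof$aspc[gt$proteins$accession, ]
  mu <- gt$proteins$lambda * gt$fold
  # each aSpC is a mean of 4 Poisson draws: se = sqrt(mu / 4)
  se <- sqrt(mu / 4)
  expect_true(mean(abs(aspc - mu) <= 3 * se) > 0.98)
  # with f = 1 everywhere, per-strain aSpC differences center on 0
  null_gt <- generate_ground_truth(n_proteins = 200, prop_diff = 0,
                                   baseline_meanlog = log(100),
                                   baseline_sdlog = 0,
                                   strains = c("WT", "mut"),
                                   product_strain = NULL, seed = 12)
  null_prof <- average_strain_profiles(
    align_lists(simulate_runs(null_gt, design))
  )
  diffs <- null_prof$aspc[, "WT"] - null_prof$aspc[, "mut"]
  expect_lt(abs(mean(diffs)), 3 * sqrt(2 * 100 / 4) / sqrt(200))
})

test_that("negative-binomial noise is overdispersed relative to Poisson", {
  gt <- generate_ground_truth(n_proteins = 1, prop_diff = 0,
                              baseline_meanlog = log(50),
                              baseline_sdlog = 0,
                              strains = c("WT", "mut"),
                              product_strain = NULL, seed = 3)
  draw_var <- function(noise) {
    des <- sim_design(strains = c("WT", "mut"), bio_reps = 2,
                      tech_reps = 50, noise = noise, dispersion = 0.5,
                      dropout = FALSE, seed = 4)
    counts <- vapply(simulate_runs(gt, des), function(r) {
      if (nrow(r$records)) r$records$spc else 0L
    }, integer(1))
    var(counts)
  }
  expect_gt(draw_var("negative_binomial"), 2 * draw_var("poisson"))
})

test_that("recovery metrics score sensitivity, FDP and FPR correctly", {
  gt <- generate_ground_truth(n_proteins = 50, prop_diff = 0.2,
                              fold_range = c(4, 4),
                              strains = c("WT", "mut"),
                              product_strain = NULL, seed = 21)
  # perfect classifier built directly from the truth
  fake_cmp <- function(status) {
    structure(
      data.frame(accession = gt$proteins$accession,
                 gene_name = "", x = 1, y = 1, dave = 0, dci = 0,
                 status = status, color_hex = "#FFFFFF",
                 stringsAsFactors = FALSE),
      sample_x = "WT", sample_y = "mut",
      thresholds = spc_thresholds(),
      class = c("spc_comparison", "data.frame"))
  }
  truth_status <- ifelse(gt$fold[, "mut"] > 1, "up_in_Y",
                         ifelse(gt$fold[, "mut"] < 1, "up_in_X",
                                "not_significant"))
  perfect <- evaluate_recovery(fake_cmp(truth_status), gt)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdp, 0)
  expect_equal(perfect$fpr, 0)

  # wrong-direction calls are not recovery
  flipped <- ifelse(truth_status == "up_in_Y", "up_in_X",
                    ifelse(truth_status == "up_in_X", "up_in_Y",
                           "not_significant"))
  expect_equal(evaluate_recovery(fake_cmp(flipped), gt)$sensitivity, 0)

  # nothing called: sensitivity 0, FDP reported 0 with a defined flag
  none <- evaluate_recovery(fake_cmp("not_significant"), gt)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$fdp, 0)
  expect_false(none$fdp_defined)

  # all-null truth with k random significant calls: FPR = k / n
  null_gt <- generate_ground_truth(n_proteins = 50, prop_diff = 0,
                                   strains = c("WT", "mut"),
                                   product_strain = NULL, seed = 22)
  k_status <- rep("not_significant", 50)
  k_status[1:7] <- "up_in_Y"
  rand <- evaluate_recovery(fake_cmp(k_status), null_gt)
  expect_equal(rand$fpr, 7 / 50)
  expect_true(is.na(rand$sensitivity))

  # disjoint accession universes are a usage error
  other <- fake_cmp(truth_status)
  other$accession <- paste0("X", seq_len(nrow(other)))
  expect_error(evaluate_recovery(other, gt), "no accessions")
})

test_that("ground-truth TSV export carries folds and labels per strain", {
  gt <- generate_ground_truth(n_proteins = 20, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth_tsv(gt, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 20L)
  expect_equal(back$fold_ubp8, unname(gt$fold[, "ubp8"]))
  expect_equal(back$label_gcn5, unname(gt$labels[, "gcn5"]))
})
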
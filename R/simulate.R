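#' Generate ground truth for a synthetic spectral-count experiment
#'
#' Draws per-protein baseline abundances (expected spectral count in the
#' reference strain) from a log-normal distribution and plants a known
#' subset of differentially abundant proteins in each mutant strain:
#' `floor(n_proteins * prop_diff)` proteins per mutant receive a fold
#' factor drawn uniformly in `fold_range`, with direction randomized 50/50
#' (a down-change uses the reciprocal fold). When the strain set contains a
#' double mutant (`product_strain`), its fold factors default to the
#' product of the single mutants' factors, emulating a synthetic
#' (combined) effect.
#'
#' @param n_proteins number of proteins in the proteome.
#' @param prop_diff fraction of proteins planted as differential per mutant
#'   (0 to 1).
#' @param fold_range length-2 numeric, lower bound > 1, fold factors drawn
#'   uniformly in this range before direction randomization.
#' @param baseline_meanlog,baseline_sdlog location and spread of the
#'   log-normal baseline abundance (expected SpC in the reference).
#' @param strains strain labels; the first element of `strains` matching
#'   `reference` is the unperturbed condition.
#' @param reference label of the unperturbed strain (fold factor 1).
#' @param product_strain strain whose fold factors are the product of all
#'   other mutants' factors, or `NULL` to draw it independently. Default:
#'   `"ubp8_gcn5"` when present in `strains`.
#' @param seed integer seed; identical seeds give identical ground truths.
#' @return An object of class `ground_truth`: list with `proteins`
#'   (data.frame of accession and baseline `lambda`), `fold` (numeric
#'   matrix, proteins x strains, reference column all 1), `labels`
#'   (character matrix: "null", "up_in_mutant", "down_in_mutant"),
#'   `reference`, `seed`.
#' @export
generate_ground_truth <- function(n_proteins = 450L, prop_diff = 0.15,
                                  fold_range = c(1.5, 4),
                                  baseline_meanlog = log(10),
                                  baseline_sdlog = 1,
                                  strains = c("WT", "ubp8", "gcn5",
                                              "ubp8_gcn5"),
                                  reference = strains[1],
                                  product_strain = if ("ubp8_gcn5" %in%
                                                       strains) "ubp8_gcn5",
                                  seed = 1L) {
  stopifnot(n_proteins >= 1L, prop_diff >= 0, prop_diff <= 1,
            length(fold_range) == 2L, fold_range[1] > 1,
            fold_range[2] >= fold_range[1],
            reference %in% strains)
  if (!is.null(product_strain)) stopifnot(product_strain %in% strains)
  set.seed(as.integer(seed))

  acc <- sprintf("SYN%04d", seq_len(n_proteins))
  lambda <- stats::rlnorm(n_proteins, baseline_meanlog, baseline_sdlog)

  fold <- base::matrix(1, nrow = n_proteins, ncol = length(strains),
                       dimnames = list(acc, strains))
  mutants <- setdiff(strains, reference)
  drawn <- setdiff(mutants, product_strain)
  n_diff <- floor(n_proteins * prop_diff)
  for (s in drawn) {
    idx <- sample.int(n_proteins, n_diff)
    f <- stats::runif(n_diff, fold_range[1], fold_range[2])
    flip <- stats::runif(n_diff) < 0.5
    f[flip] <- 1 / f[flip]
    fold[idx, s] <- f
  }
  if (!is.null(product_strain) && length(drawn) > 0L) {
    fold[, product_strain] <-
      apply(fold[, drawn, drop = FALSE], 1L, prod)
  }

  labels <- base::matrix("null", nrow = n_proteins, ncol = length(strains),
                         dimnames = list(acc, strains))
  labels[fold > 1] <- "up_in_mutant"
  labels[fold < 1] <- "down_in_mutant"

  structure(
    list(proteins = data.frame(accession = acc, lambda = lambda,
                               stringsAsFactors = FALSE),
         fold = fold, labels = labels, reference = reference,
         seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Simulation design for synthetic spectral-count runs
#'
#' @param strains strain labels (must match the ground truth's).
#' @param bio_reps biological preparations per strain.
#' @param tech_reps technical replicates per preparation.
#' @param noise count noise model: `"poisson"` (default) or
#'   `"negative_binomial"`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   ignored for Poisson.
#' @param dropout if `TRUE` (default), a protein's identification in a run
#'   additionally requires a detection draw with probability
#'   `1 - exp(-mu / dropout_scale)`, so low-abundance proteins are
#'   intermittently identified.
#' @param dropout_scale scale of the detection-probability curve.
#' @param bio_sd standard deviation (log scale) of an optional per-protein
#'   biological-preparation effect; 0 disables it.
#' @param seed integer seed for the simulation.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(strains = c("WT", "ubp8", "gcn5", "ubp8_gcn5"),
                       bio_reps = 2L, tech_reps = 2L,
                       noise = c("poisson", "negative_binomial"),
                       dispersion = 0.05, dropout = TRUE,
                       dropout_scale = 3, bio_sd = 0, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(bio_reps >= 1L, tech_reps >= 1L, dropout_scale > 0,
            bio_sd >= 0)
  if (noise == "negative_binomial") stopifnot(dispersion > 0)
  structure(
    list(strains = strains, bio_reps = as.integer(bio_reps),
         tech_reps = as.integer(tech_reps), noise = noise,
         dispersion = dispersion, dropout = dropout,
         dropout_scale = dropout_scale, bio_sd = bio_sd,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

#' Simulate identification lists from a ground truth
#'
#' Draws one run list per strain x biological preparation x technical
#' replicate. The spectral count of protein i in strain s has mean
#' `lambda_i * fold_{i,s}` (times an optional log-normal
#' biological-preparation effect) under the design's noise model. Proteins
#' with a simulated count of 0, or failing the detection (dropout) draw,
#' are omitted from that run's list, emulating non-identification; the
#' unique-peptide count of an included record is simulated >= 1.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param design a [sim_design()]; its strains must all be columns of the
#'   ground truth's fold matrix.
#' @return A list of [run_list] objects, ordered by strain, then
#'   preparation, then technical replicate.
#' @export
simulate_runs <- function(gt, design = sim_design()) {
  stopifnot(inherits(gt, "ground_truth"), inherits(design, "sim_design"))
  missing_strains <- setdiff(design$strains, colnames(gt$fold))
  if (length(missing_strains) > 0L) {
    stop("design strains absent from ground truth: ",
         paste(missing_strains, collapse = ", "), call. = FALSE)
  }
  set.seed(design$seed)
  n <- nrow(gt$proteins)
  acc <- gt$proteins$accession
  runs <- list()
  for (s in design$strains) {
    mu_s <- gt$proteins$lambda * gt$fold[, s]
    for (b in seq_len(design$bio_reps)) {
      mu_b <- if (design$bio_sd > 0) {
        mu_s * stats::rlnorm(n, -design$bio_sd^2 / 2, design$bio_sd)
      } else {
        mu_s
      }
      for (t in seq_len(design$tech_reps)) {
        spc <- if (design$noise == "poisson") {
          stats::rpois(n, mu_b)
        } else {
          stats::rnbinom(n, mu = mu_b, size = 1 / design$dispersion)
        }
        keep <- spc > 0L
        if (design$dropout) {
          p_det <- 1 - exp(-mu_b / design$dropout_scale)
          keep <- keep & stats::runif(n) < p_det
        }
        idx <- which(keep)
        rec <- data.frame(
          accession = acc[idx],
          gene_name = sub("^SYN", "GEN", acc[idx]),
          description = "",
          unique_peptides = 1L + stats::rpois(length(idx),
                                              log1p(spc[idx])),
          spc = spc[idx],
          stringsAsFactors = FALSE
        )
        runs[[length(runs) + 1L]] <-
          run_list(rec, strain = s, bio_rep = b, tech_rep = t)
      }
    }
  }
  runs
}

#' Score recovery of planted differential proteins
#'
#' Compares a pairwise comparison's significance calls against the ground
#' truth for the mutant strain involved. A planted protein counts as
#' recovered only when it is called significant in the correct direction;
#' planted proteins missing from the comparison (never detected) count as
#' misses. The false-positive rate is computed among null proteins that
#' were comparable (detected in at least one of the two strains).
#'
#' @param result a [compare_strains()] result for reference vs mutant (in
#'   either orientation).
#' @param gt the [generate_ground_truth()] used to simulate the data.
#' @param mutant mutant strain label; by default inferred as whichever of
#'   the comparison's samples is not the ground truth's reference.
#' @return A list of class `recovery_metrics`: `sensitivity`, `fdp`
#'   (false-discovery proportion among significant calls; 0 with
#'   `fdp_defined = FALSE` when nothing is called), `fpr`, counts
#'   (`n_true_diff`, `n_recovered`, `n_significant`, `n_false`,
#'   `n_null_comparable`), and per-stratum sensitivities `by_fold`
#'   (effect-size bins) and `by_lambda` (baseline-abundance terciles).
#' @export
evaluate_recovery <- function(result, gt, mutant = NULL) {
  stopifnot(inherits(result, "spc_comparison"),
            inherits(gt, "ground_truth"))
  sx <- attr(result, "sample_x")
  sy <- attr(result, "sample_y")
  if (is.null(mutant)) {
    mutant <- setdiff(c(sx, sy), gt$reference)
    if (length(mutant) != 1L) {
      stop("cannot infer the mutant strain; pass `mutant` explicitly",
           call. = FALSE)
    }
  }
  if (!mutant %in% colnames(gt$fold)) {
    stop("strain not in ground truth: ", mutant, call. = FALSE)
  }
  if (!any(result$accession %in% gt$proteins$accession)) {
    stop("comparison and ground truth share no accessions", call. = FALSE)
  }
  mutant_is_y <- identical(sy, mutant)
  up_in_mutant_status <- if (mutant_is_y) "up_in_Y" else "up_in_X"
  down_in_mutant_status <- if (mutant_is_y) "up_in_X" else "up_in_Y"

  fold <- gt$fold[, mutant]
  truth <- data.frame(accession = gt$proteins$accession,
                      lambda = gt$proteins$lambda,
                      fold = unname(fold), stringsAsFactors = FALSE)
  m <- match(truth$accession, result$accession)
  truth$status <- ifelse(is.na(m), "not_comparable", result$status[m])

  is_diff <- truth$fold != 1
  called_sig <- truth$status %in% c("up_in_X", "up_in_Y")
  correct_dir <- (truth$fold > 1 &
                    truth$status == up_in_mutant_status) |
    (truth$fold < 1 & truth$status == down_in_mutant_status)
  recovered <- is_diff & correct_dir

  n_true_diff <- sum(is_diff)
  n_sig <- sum(called_sig)
  n_false <- sum(called_sig & !is_diff)
  null_comparable <- !is_diff & truth$status != "not_comparable"

  sens_in <- function(sel) {
    if (sum(is_diff & sel) == 0L) return(NA_real_)
    sum(recovered & sel) / sum(is_diff & sel)
  }
  effect <- pmax(truth$fold, 1 / truth$fold)
  fold_bins <- cut(effect, c(1, 1.5, 2, 3, Inf), right = FALSE,
                   labels = c("[1,1.5)", "[1.5,2)", "[2,3)", ">=3"))
  by_fold <- vapply(levels(fold_bins), function(lv) {
    sens_in(!is.na(fold_bins) & fold_bins == lv)
  }, numeric(1))
  lam_breaks <- stats::quantile(truth$lambda, c(0, 1 / 3, 2 / 3, 1))
  lam_bins <- cut(truth$lambda, unique(lam_breaks),
                  include.lowest = TRUE)
  by_lambda <- vapply(levels(lam_bins), function(lv) {
    sens_in(!is.na(lam_bins) & lam_bins == lv)
  }, numeric(1))

  structure(
    list(
      sensitivity = if (n_true_diff == 0L) NA_real_ else
        sum(recovered) / n_true_diff,
      fdp = if (n_sig == 0L) 0 else n_false / n_sig,
      fdp_defined = n_sig > 0L,
      fpr = if (sum(null_comparable) == 0L) NA_real_ else
        sum(called_sig & null_comparable) / sum(null_comparable),
      n_true_diff = n_true_diff,
      n_recovered = sum(recovered),
      n_significant = n_sig,
      n_false = n_false,
      n_null_comparable = sum(null_comparable),
      by_fold = by_fold,
      by_lambda = by_lambda,
      mutant = mutant
    ),
    class = "recovery_metrics"
  )
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("<recovery_metrics> mutant %s\n", x$mutant))
  cat(sprintf("  sensitivity %.3f (%d/%d) | FDP %.3f%s | FPR %.4f\n",
              x$sensitivity, x$n_recovered, x$n_true_diff, x$fdp,
              if (x$fdp_defined) "" else " (no calls)", x$fpr))
  invisible(x)
}

#' Write a ground truth as TSV
#'
#' One row per protein: accession, baseline lambda, then the fold factor
#' and label for every strain.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_tsv <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  df <- gt$proteins
  for (s in colnames(gt$fold)) {
    df[[paste0("fold_", s)]] <- gt$fold[, s]
    df[[paste0("label_", s)]] <- gt$labels[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
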
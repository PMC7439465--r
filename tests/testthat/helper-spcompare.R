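# fixtures and independent oracles used across test files

make_records <- function(accession, spc, unique_peptides = NULL,
                         gene_name = NULL) {
  n <- length(accession)
  data.frame(
    accession = accession,
    gene_name = if (is.null(gene_name)) sprintf("G%d", seq_len(n)) else
      gene_name,
    description = sprintf("protein %d", seq_len(n)),
    unique_peptides = if (is.null(unique_peptides)) rep(2L, n) else
      as.integer(unique_peptides),
    spc = as.integer(spc),
    stringsAsFactors = FALSE
  )
}

make_run <- function(accession, spc, strain = "WT", bio_rep = 1L,
                     tech_rep = 1L, ...) {
  run_list(make_records(accession, spc, ...), strain = strain,
           bio_rep = bio_rep, tech_rep = tech_rep)
}

# brute-force alignment oracle: per-accession dictionary lookup,
# independent of align_lists's matrix construction
oracle_align <- function(runs) {
  accs <- unique(unlist(lapply(runs, function(r) r$records$accession)))
  out <- sapply(runs, function(r) {
    vapply(accs, function(a) {
      hit <- which(r$records$accession == a)
      if (length(hit) == 0L) 0L else r$records$spc[hit]
    }, integer(1))
  })
  out <- matrix(out, nrow = length(accs),
                dimnames = list(accs, vapply(runs, `[[`, character(1),
                                             "run_id")))
  out[rowSums(out) > 0, , drop = FALSE]
}

# brute-force Venn oracle: walk the union, record each element's
# membership pattern, tally patterns
oracle_venn_counts <- function(sets) {
  universe <- unique(unlist(sets))
  patterns <- vapply(universe, function(el) {
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(patterns)
}

random_runs <- function(n_runs = 3L, n_acc_pool = 12L, max_spc = 30L) {
  pool <- sprintf("P%03d", seq_len(n_acc_pool))
  lapply(seq_len(n_runs), function(j) {
    acc <- sample(pool, sample(2:n_acc_pool, 1))
    make_run(acc, sample.int(max_spc, length(acc), replace = TRUE),
             strain = paste0("S", j))
  })
}
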
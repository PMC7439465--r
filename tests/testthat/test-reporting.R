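test_that("presence sets honor the min_runs detection threshold", {
  runs <- c(
    lapply(1:4, function(i) {
      make_run(if (i == 1) c("P1", "P2") else "P2",
               if (i == 1) c(3, 5) else 5,
               strain = "WT", bio_rep = (i + 1) %/% 2,
               tech_rep = 2 - i %% 2)
    }),
    list(make_run("P3", 7, strain = "ubp8"))
  )
  m <- align_lists(runs)
  s1 <- presence_sets(m, min_runs = 1)
  expect_true("P1" %in% s1$WT)       # detected in 1 of 4 WT runs
  s2 <- presence_sets(m, min_runs = 2)
  expect_false("P1" %in% s2$WT)
  expect_true("P2" %in% s2$WT)
  expect_false("P3" %in% s1$WT)
  expect_equal(s1$ubp8, "P3")
})

test_that("venn_partition enumerates disjoint regions with reference aggregates", {
  sets <- list(A = c("1", "2"), B = "2", C = character(0),
               D = c("2", "3"))
  v <- venn_partition(sets, reference = "A")
  counts <- setNames(v$regions$count, v$regions$region)
  expect_equal(unname(counts[["A"]]), 1)       # {1}
  expect_equal(unname(counts[["A&B&D"]]), 1)   # {2}
  expect_equal(unname(counts[["D"]]), 1)       # {3}
  expect_equal(sum(v$regions$count), 3)
  expect_equal(nrow(v$regions), 15)            # 2^4 - 1 regions
  expect_equal(v$with_reference, 2)
  expect_equal(v$absent_from_reference, 1)
  expect_setequal(v$members[["A&B&D"]], "2")

  same <- replicate(4, c("x", "y"), simplify = FALSE)
  names(same) <- LETTERS[1:4]
  v2 <- venn_partition(same)
  expect_equal(v2$regions$count[v2$regions$region == "A&B&C&D"], 2)
  expect_equal(sum(v2$regions$count), 2)

  disjoint <- list(A = "1", B = "2", C = "3", D = "4")
  v3 <- venn_partition(disjoint)
  expect_true(all(v3$regions$count[v3$regions$degree > 1] == 0))
  expect_equal(sum(v3$regions$count[v3$regions$degree == 1]), 4)

  expect_error(venn_partition(list(A = "1")), "at least 2")
})

test_that("venn regions partition the union on random instances", {
  withr::local_seed(77)
  for (i in 1:50) {
    pool <- sprintf("P%02d", 1:15)
    sets <- lapply(1:4, function(j) sample(pool, sample(0:15, 1)))
    names(sets) <- c("WT", "ubp8", "gcn5", "ubp8_gcn5")
    v <- venn_partition(sets)
    expect_equal(sum(v$regions$count), v$union_size)
    expect_equal(v$with_reference + v$absent_from_reference,
                 v$union_size)
    # agree with the brute-force membership-pattern oracle
    oracle <- oracle_venn_counts(sets)
    got <- setNames(v$regions$count, v$regions$region)
    for (pat in names(oracle)) {
      expect_equal(unname(got[[pat]]), unname(oracle[[pat]]))
    }
    # each accession appears in exactly one region
    all_members <- unlist(v$members)
    expect_equal(anyDuplicated(all_members), 0L)
    expect_setequal(all_members, unique(unlist(sets)))
  }
})

make_three_comparisons <- function() {
  runs <- list(
    make_run(c("P1", "P2", "P3"), c(10, 5, 8), strain = "WT"),
    make_run(c("P1", "P2", "P3"), c(2, 5, 8), strain = "ubp8"),
    make_run(c("P1", "P2", "P3"), c(10, 5, 8), strain = "gcn5"),
    make_run(c("P1", "P2", "P3"), c(2, 5, 8), strain = "ubp8_gcn5")
  )
  prof <- average_strain_profiles(align_lists(runs))
  cmps <- lapply(c("ubp8", "gcn5", "ubp8_gcn5"), function(s) {
    compare_strains(prof, "WT", s)
  })
  names(cmps) <- paste0("WT_vs_", c("ubp8", "gcn5", "ubp8_gcn5"))
  cmps
}

test_that("the differential table keeps proteins significant in >= 1 comparison", {
  cmps <- make_three_comparisons()
  ann <- data.frame(accession = c("P1", "P2"),
                    class = c("glycolysis", "fermentation"),
                    human_orthologue = c("H1", ""),
                    interactions = c("P/G", ""),
                    stringsAsFactors = FALSE)
  tab <- build_differential_table(cmps, ann)
  # P1 changes in ubp8 and the double mutant only
  expect_equal(tab$accession, "P1")
  expect_equal(tab$function_class, "glycolysis")
  expect_equal(tab$DAve_WT_vs_ubp8, 1.33)
  expect_equal(tab$DAve_WT_vs_gcn5, 0)
  expect_equal(tab$color_WT_vs_gcn5, "#FFFFFF")
  expect_false(tab$color_WT_vs_ubp8 == "#FFFFFF")
  # row set equals union of per-comparison significant sets
  sig_union <- unique(unlist(lapply(cmps, function(cm) {
    cm$accession[cm$status %in% c("up_in_X", "up_in_Y")]
  })))
  expect_setequal(tab$accession, sig_union)
  # unannotated significant proteins fall back to "unknown"
  tab2 <- build_differential_table(cmps, annotations = NULL)
  expect_equal(tab2$function_class, "unknown")
})

test_that("an all-null experiment yields an empty differential table", {
  runs <- list(make_run("P1", 5, strain = "WT"),
               make_run("P1", 5, strain = "ubp8"))
  prof <- average_strain_profiles(align_lists(runs))
  tab <- build_differential_table(list(compare_strains(prof, "WT",
                                                       "ubp8")))
  expect_equal(nrow(tab), 0L)
  expect_true(all(c("accession", "function_class") %in% names(tab)))
})

test_that("network export filters edges at an inclusive confidence threshold", {
  nodes <- data.frame(accession = c("P1", "P2", "P3"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(acc_a = c("P1", "P1", "P2"),
                      acc_b = c("P2", "P3", "P3"),
                      score = c(0.39, 0.40, 0.9),
                      stringsAsFactors = FALSE)
  net <- export_network(nodes, edges, min_score = 0.4)
  expect_equal(nrow(net$edges), 2L)
  expect_false(any(net$edges$score < 0.4))
  expect_true(0.40 %in% net$edges$score)   # boundary kept
  # isolated node P1 (after filtering) is retained in the node table
  expect_equal(nrow(net$nodes), 3L)

  # unknown accession: warn and skip that edge
  bad <- rbind(edges, data.frame(acc_a = "P1", acc_b = "P99",
                                 score = 0.8))
  expect_warning(net2 <- export_network(nodes, bad), "P99")
  expect_equal(nrow(net2$edges), 2L)

  empty <- export_network(nodes, edges[0, ])
  expect_equal(nrow(empty$edges), 0L)
  expect_error(export_network(nodes, transform(edges, score = score + 1)),
               "\\[0, 1\\]")
})
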
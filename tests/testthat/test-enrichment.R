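test_that("upper tail matches small-case enumeration and closed forms", {
  expect_identical(hypergeom_upper_tail(0, 3, 2, 5), 1)
  # full enumeration of the C(5,2) = 10 equally likely draws
  expect_equal(hypergeom_upper_tail(2, 3, 2, 5), 3 / 10, tolerance = 1e-12)
  # spot checks across mixed regimes against the no-log enumeration oracle
  set.seed(2)
  for (i in 1:50) {
    N <- sample(2:40, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    x <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper_tail(x, K, n, N),
                 hyper_upper_enum(x, K, n, N), tolerance = 1e-12)
  }
  # and against the standard distribution function at realistic scale
  expect_equal(hypergeom_upper_tail(4, 123, 120, 11017),
               phyper(3, 123, 11017 - 123, 120, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(3, 2, 5, 10),
               class = "dentproteo_validation_error")
})

test_that("upper tail is monotone in x and N; pmf sums to one", {
  K <- 30; n <- 25; N <- 200
  tails <- hypergeom_upper_tail(0:min(K, n), K, n, N)
  expect_true(all(diff(tails) < 0))
  # enlarging the background makes any given overlap rarer
  for (x in c(1, 3, 7))
    expect_gt(hypergeom_upper_tail(x, K, n, N),
              hypergeom_upper_tail(x, K, n, N + 500))
  pmf <- tails - c(tails[-1], 0)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
})

test_that("enrichment ranks significant pathways by entity ratio", {
  uni <- sprintf("U%03d", 1:500)
  query <- uni[1:40]
  pws <- list(
    list(pathway_id = "big", name = "whole background", members = uni),
    list(pathway_id = "hit", name = "mostly query", members = uni[1:25]),
    list(pathway_id = "med", name = "half query",
         members = c(uni[1:10], uni[101:115])),
    list(pathway_id = "null", name = "unrelated", members = uni[401:430]))
  res <- enrich(query, pws, N = 500)
  expect_equal(res$entities_ratio[res$pathway_id == "big"], 1)
  expect_equal(res$p_value[res$pathway_id == "big"], 1)
  expect_equal(res$x[res$pathway_id == "hit"], 25)
  sig <- res[res$significant, ]
  expect_identical(sig$rank, seq_len(nrow(sig)))
  expect_true(all(diff(sig$entities_ratio) <= 0))
  expect_true(all(is.na(res$rank[!res$significant])))
  # pathways without any query member are absent
  pws2 <- c(pws, list(list(pathway_id = "zero", name = "no overlap",
                           members = uni[451:460])))
  expect_false("zero" %in% enrich(query, pws2, N = 500)$pathway_id)
})

test_that("a strongly planted pathway attains the smallest p almost always", {
  uni <- sprintf("U%03d", 1:500)
  planted <- uni[1:50]
  wins <- 0L
  for (s in 1:100) {
    ps <- generate_pathway_sets(uni, planted, n_pathways = 100,
                                size_range = c(15, 60), n_enriched = 1,
                                enriched_frac = 0.8, seed = 2000 + s)
    res <- enrich(planted, ps$pathways, N = 500)
    if (res$pathway_id[which.min(res$p_value)] == ps$enriched_ids) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 95)
})

test_that("background inference recovers N from printed pairs", {
  expect_equal(infer_background(10, 0.5)$N, 20)
  one <- infer_background(573, 0.0520)
  expect_gte(one$N, one$intervals[1, "lower"])
  expect_true(one$intervals[1, "lower"] <= 11017 &
                11017 <= one$intervals[1, "upper"])
  expect_equal(unname(one$intervals[1, ]), c(11009, 11029))
  five <- infer_background(c(573, 532, 191, 180, 151),
                           c(0.0520, 0.0483, 0.0173, 0.0163, 0.0137))
  expect_lt(abs(five$N - 11017), 10.5)
  ref <- reference_enrichment()
  full <- infer_background(ref$total, ref$entities_ratio)
  expect_equal(unname(full$intersection), c(11015, 11023))
  expect_true(full$N >= 11015 && full$N <= 11023)
  # contradictory pairs: warning, but a least-squares N is still returned
  expect_warning(bad <- infer_background(c(10, 10), c(0.5, 0.9)))
  expect_true(is.finite(bad$N))
})

test_that("category profiles count terms over the query with zeros kept", {
  cm <- data.frame(accession = c("P1", "P2", "P3", "P1"),
                   namespace = c("Function", "Function", "Function",
                                 "Process"),
                   term = c("Binding", "Binding", "Transport", "Metabolism"),
                   stringsAsFactors = FALSE)
  prof <- profile_categories(c("P1", "P2"), cm)
  fun <- prof[prof$namespace == "Function", ]
  expect_equal(fun$count[fun$term == "Binding"], 2L)
  expect_equal(fun$count[fun$term == "Transport"], 0L)
  expect_equal(fun$proportion[fun$term == "Binding"], 1)
  expect_equal(attr(prof, "unannotated")[["Process"]], 1L)
  expect_equal(nrow(profile_categories(character(0), cm)), 0)
})

test_that("profile counts equal a brute-force tally on random annotation", {
  set.seed(77)
  acc <- sprintf("P%02d", 1:50)
  cm <- data.frame(accession = sample(acc, 120, replace = TRUE),
                   namespace = sample(c("ns1", "ns2"), 120, replace = TRUE),
                   term = sample(letters[1:6], 120, replace = TRUE),
                   stringsAsFactors = FALSE)
  query <- sample(acc, 20)
  prof <- profile_categories(query, cm)
  for (i in seq_len(nrow(prof))) {
    manual <- length(unique(cm$accession[cm$namespace == prof$namespace[i] &
                                           cm$term == prof$term[i] &
                                           cm$accession %in% query]))
    expect_equal(prof$count[i], manual)
  }
})
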
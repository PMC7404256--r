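test_that("overlap_coefficient matches the packaged module pair", {
  fix <- table1_fixture()
  expect_equal(overlap_coefficient(fix$M17, fix$M18), 0.5)
  expect_equal(overlap_coefficient(fix$M17, fix$M17), 1.0)
  expect_equal(overlap_coefficient(c("1", "2"), c("3", "4")), 0.0)
  expect_equal(overlap_coefficient(fix$M17, fix$M18),
               overlap_coefficient(fix$M18, fix$M17))
  # containment gives 1 exactly
  expect_equal(overlap_coefficient(c("1", "2"), c("1", "2", "3")), 1.0)
  expect_error(overlap_coefficient(character(), "1"), "empty")
})

test_that("is_overlapped decides the 2/3 boundary in exact arithmetic", {
  fix <- table1_fixture()
  expect_false(is_overlapped(fix$M17, fix$M18))          # 0.5 < 2/3
  expect_true(is_overlapped(c("1", "2"), c("1", "2", "3"))) # containment
  expect_true(is_overlapped(c("1", "2", "3"), c("1", "2", "9", "8")))
  # |intersect| = 2, min = 3: exactly 2/3, counts as overlapped
  expect_false(is_overlapped(c("1", "4", "5"), c("1", "2", "3")))
})

test_that("size_filter keeps modules of at least min_size genes in order", {
  mods <- lapply(list(c("a", "b"), c("a", "b", "c"), letters[1:5]),
                 function(g) list(genes = g))
  kept <- size_filter(mods, 3)
  expect_equal(vapply(kept, function(m) length(m$genes), integer(1)), c(3L, 5L))
  expect_length(size_filter(mods, 1), 3L)
  # every packaged fixture module has at least three genes
  fix_mods <- lapply(table1_fixture(), function(g) list(genes = g))
  expect_length(size_filter(fix_mods, 3), 26L)
})

test_that("deg_containment_filter supports any/all disease modes", {
  mods <- list(
    list(genes = c("a", "b", "c")),
    list(genes = c("x", "y", "z")),
    list(genes = c("a", "q", "r"))
  )
  conc <- list(d1 = c("a"), d2 = c("b", "q"), d3 = c("zz"))
  any_kept <- deg_containment_filter(mods, conc, mode = "any")
  expect_length(any_kept, 2L)           # module 2 disjoint from the union
  all_kept <- deg_containment_filter(mods, conc, mode = "all")
  expect_length(all_kept, 0L)           # no module meets every set (d3 empty hit)
  conc2 <- list(d1 = c("a"), d2 = c("b"))
  expect_length(deg_containment_filter(mods, conc2, mode = "all"), 1L)
})

test_that("enrich_terms matches the closed-form hypergeometric example", {
  background <- sprintf("g%03d", 1:100)
  ann <- annotation_map(
    gene = background[1:5], namespace = rep("BP", 5), term = rep("T", 5),
    background = background
  )
  res <- enrich_terms(background[1:5], ann, "BP")
  expect_equal(res$k, 5L)
  expect_equal(res$p_raw, 1 / choose(100, 5), tolerance = 1e-9)

  # a term annotating every background gene is never enriched
  ann2 <- annotation_map(background, rep("BP", 100), rep("ALL", 100))
  res2 <- enrich_terms(background[1:10], ann2, "BP")
  expect_equal(res2$p_raw, 1)

  # k = 0 terms are omitted; unknown query genes error
  ann3 <- annotation_map(
    c(background[1:3], background[50:60]),
    rep("BP", 14), rep(c("hit", "miss"), c(3, 11)),
    background = background
  )
  res3 <- enrich_terms(background[1:3], ann3, "BP")
  expect_identical(res3$term, "hit")
  expect_error(enrich_terms("absent", ann3, "BP"), "absent")
})

test_that("enrich_terms agrees with brute-force tail summation for N <= 30", {
  set.seed(33)
  for (rep_i in 1:20) {
    N <- sample(5:30, 1)
    background <- sprintf("b%02d", 1:N)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    term_genes <- sample(background, K)
    query <- sample(background, n)
    ann <- annotation_map(term_genes, rep("BP", K), rep("T", K),
                          background = background)
    k <- length(intersect(term_genes, query))
    if (k == 0) next
    res <- enrich_terms(query, ann, "BP")
    expect_equal(res$p_raw, brute_hyper_tail(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(12)
  background <- sprintf("g%03d", 1:60)
  gene <- character(); ns <- character(); term <- character()
  for (t in 1:8) {
    members <- sample(background, sample(3:20, 1))
    gene <- c(gene, members)
    ns <- c(ns, rep("BP", length(members)))
    term <- c(term, rep(sprintf("T%d", t), length(members)))
  }
  ann <- annotation_map(gene, ns, term, background = background)
  res <- enrich_terms(sample(background, 15), ann, "BP")
  expect_true(all(res$p_adjusted >= res$p_raw))
  # sorted by p_raw, the step-up adjusted values are non-decreasing
  expect_true(all(diff(res$p_adjusted[order(res$p_raw)]) >= -1e-15))
})

test_that("term_overlap_filter applies per-namespace proportions", {
  mod_genes <- sprintf("m%02d", 1:6)
  sim <- simulate_annotation(list(mod_genes), enriched_terms_per_module = 3,
                             n_background_genes = 300, seed = 5)
  ann <- sim$annotation
  mods <- list(list(genes = mod_genes))

  # reference identical to everything significant: proportions 1, kept
  ref_all <- do.call(rbind, lapply(c("BP", "MF", "CC"), function(nsp) {
    res <- enrich_terms(mod_genes, ann, nsp)
    data.frame(namespace = nsp, term = res$term[res$significant],
               stringsAsFactors = FALSE)
  }))
  kept <- term_overlap_filter(mods, ref_all, ann, min_proportion = 0.99)
  expect_length(kept, 1L)
  expect_true(all(kept[[1]]$term_proportions == 1))

  # zero common MF terms: dropped at any positive min_proportion
  ref_no_mf <- ref_all[ref_all$namespace != "MF", , drop = FALSE]
  ref_no_mf <- rbind(ref_no_mf, data.frame(namespace = "MF", term = "bogus"))
  expect_length(term_overlap_filter(mods, ref_no_mf, ann,
                                    min_proportion = 0.01), 0L)

  # a module with no significant terms is dropped with a logged reason:
  # its only hit term covers the whole background (p_raw = 1)
  stray <- list(list(genes = c("m01", "zz1", "zz2")))
  universe <- c("m01", "zz1", "zz2", sprintf("q%02d", 1:40))
  ann_small <- annotation_map(universe, rep("BP", 43), rep("T1", 43))
  expect_message(
    out <- term_overlap_filter(stray, data.frame(namespace = "BP", term = "T1"),
                               ann_small, min_proportion = 0,
                               namespaces = "BP"),
    "dropped"
  )
  expect_length(out, 0L)
})

test_that("term proportion arithmetic: 3 of 6 shared terms gives 0.5", {
  # six BP terms significant for the module, three shared with the reference
  mod_genes <- sprintf("m%02d", 1:8)
  background <- c(mod_genes, sprintf("b%03d", 1:400))
  gene <- character(); term <- character()
  for (t in 1:6) {
    members <- c(mod_genes, sample(sprintf("b%03d", 1:400), 4))
    gene <- c(gene, members)
    term <- c(term, rep(sprintf("T%d", t), length(members)))
  }
  ann <- annotation_map(gene, rep("BP", length(gene)), term,
                        background = background)
  ref <- data.frame(namespace = "BP", term = c("T1", "T2", "T3"))
  kept <- term_overlap_filter(list(list(genes = mod_genes)), ref, ann,
                              min_proportion = 0.2, namespaces = "BP")
  expect_length(kept, 1L)
  expect_equal(unname(kept[[1]]$term_proportions["BP"]), 0.5)
})

test_that("disease_term_filter requires all namespaces for every disease", {
  mod_genes <- sprintf("m%02d", 1:6)
  sim <- simulate_annotation(list(mod_genes), enriched_terms_per_module = 2,
                             n_background_genes = 300, seed = 6)
  ann <- sim$annotation
  mods <- list(list(genes = mod_genes))
  sig <- lapply(c("BP", "MF", "CC"), function(nsp) {
    res <- enrich_terms(mod_genes, ann, nsp)
    data.frame(namespace = nsp, term = res$term[res$significant],
               stringsAsFactors = FALSE)
  })
  full <- do.call(rbind, sig)

  # one shared term per namespace per disease: kept
  expect_length(
    disease_term_filter(mods, list(d1 = full, d2 = full), ann), 1L
  )
  # missing CC terms for one disease: dropped
  no_cc <- full[full$namespace != "CC", , drop = FALSE]
  expect_length(
    disease_term_filter(mods, list(d1 = full, d2 = no_cc), ann), 0L
  )
  # terms shared with 1 of 2 diseases only: dropped
  bogus <- data.frame(namespace = c("BP", "MF", "CC"),
                      term = c("x", "y", "z"))
  expect_length(
    disease_term_filter(mods, list(d1 = full, d2 = bogus), ann), 0L
  )
})

test_that("neighbor_score sums edge weights into the module", {
  net <- weighted_network(
    c("m1", "m2", "m1", "n1"), c("n1", "n1", "m2", "n2"),
    c(0.3, 0.5, 0.9, 0.4)
  )
  expect_equal(neighbor_score(net, c("m1", "m2"), "n1"), 0.8)
  expect_equal(neighbor_score(net, c("m1", "m2"), "n2"), 0)
  star <- weighted_network(rep("hub", 4), sprintf("m%d", 1:4), rep(1, 4))
  expect_equal(neighbor_score(star, sprintf("m%d", 1:4), "hub"), 4.0)
  expect_error(neighbor_score(net, c("m1", "m2"), "m1"), "inside")
})

test_that("neighbor_threshold returns the rank-th sampled score", {
  # constant score distribution: the threshold is that score
  net <- weighted_network(c("m1", "m1"), c("a", "b"), c(0.7, 0.7))
  expect_equal(neighbor_threshold(net, "m1", n_samples = 100, rank = 10,
                                  seed = 1), 0.7)

  # two scores {1.0, 0.2}: rank 50 of 1000 is the high score w.h.p.
  net2 <- weighted_network(c("m1", "m1", "m2"), c("a", "b", "a"),
                           c(0.8, 0.2, 0.2))
  expect_equal(neighbor_threshold(net2, c("m1", "m2"), n_samples = 1000,
                                  rank = 50, seed = 2), 1.0)

  # rank = n_samples: the sampled minimum
  thr_min <- neighbor_threshold(net2, c("m1", "m2"), n_samples = 2000,
                                rank = 2000, seed = 3)
  expect_equal(thr_min, 0.2)

  expect_error(neighbor_threshold(net2, c("m1", "m2"), n_samples = 10,
                                  rank = 11), "exceeds")
  isolated <- weighted_network("x", "y", 1)
  expect_error(neighbor_threshold(isolated, c("x", "y")), "no first-order")
})

test_that("neighbor_threshold is stable across seeds on a fixed network", {
  set.seed(88)
  hub <- sprintf("m%d", 1:5)
  leaves <- sprintf("n%02d", 1:40)
  from <- character(); to <- character(); w <- numeric()
  for (lf in leaves) {
    deg <- sample(1:3, 1)
    ms <- sample(hub, deg)
    from <- c(from, ms); to <- c(to, rep(lf, deg))
    w <- c(w, runif(deg, 0.1, 1))
  }
  net <- weighted_network(from, to, w)
  t1 <- neighbor_threshold(net, hub, n_samples = 20000, rank = 50, seed = 1)
  t2 <- neighbor_threshold(net, hub, n_samples = 20000, rank = 50, seed = 2)
  scores <- sort(sapply(first_order_neighbors(net, hub),
                        function(g) neighbor_score(net, hub, g)),
                 decreasing = TRUE)
  # both seeds land on a top-order-statistic score
  expect_true(t1 %in% scores[1:3])
  expect_true(t2 %in% scores[1:3])
})

test_that("conserved_neighbors uses a strict inequality", {
  net <- weighted_network(
    c("m1", "m1", "m1"), c("a", "b", "c"), c(0.8, 0.5, 0.5)
  )
  expect_identical(conserved_neighbors(net, "m1", 0.5), "a")
  expect_identical(conserved_neighbors(net, "m1", 99), character())
  expect_setequal(conserved_neighbors(net, "m1", 0), c("a", "b", "c"))
})

test_that("pathway_overlap_count is the intersection size", {
  expect_equal(pathway_overlap_count(c("p1", "p2", "p3", "p4"),
                                     c("p1", "p2", "p3", "p4")), 4L)
  expect_equal(pathway_overlap_count(c("p1"), c("p2")), 0L)
  expect_equal(pathway_overlap_count(c("p1", "p2", "p3"),
                                     c("p2", "p3", "p4")), 2L)
})

test_that("GMT and annotation files round-trip", {
  sets <- list(s1 = c("1", "2", "3"), s2 = c("9", "8"))
  p <- tempfile(fileext = ".gmt")
  write_gmt(sets, p, descriptions = c("first", "second"))
  back <- read_gmt(p)
  expect_identical(back$s1, sets$s1)
  expect_identical(back$s2, sets$s2)

  ann <- annotation_map(c("1", "2"), c("BP", "MF"), c("t1", "t2"),
                        background = c("1", "2", "3"))
  pa <- tempfile(fileext = ".tsv")
  write_annotation(ann, pa)
  back2 <- read_annotation(pa, background = c("1", "2", "3"))
  expect_identical(back2$entries, ann$entries)
  expect_identical(back2$background, ann$background)
})
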
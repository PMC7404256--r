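test_that("heaviness expands the indicator form of the objective", {
  # single 0.8 edge: the 1/2 cancels the symmetric double count
  a <- array(0, c(3, 3, 2))
  a[1, 2, 1] <- a[2, 1, 1] <- 0.8
  tens <- as_tensor(a)
  expect_equal(heaviness(tens, c("g01", "g02"), "L1"), 0.8)

  # empty selections vanish
  expect_equal(heaviness(tens, character(), "L1"), 0)
  expect_equal(heaviness(tens, c("g01", "g02"), character()), 0)

  # 3-clique of unit weights on 2 layers: 3 edges x 2 layers
  b <- array(0, c(3, 3, 2))
  for (k in 1:2) { b[, , k] <- 1; diag(b[, , k]) <- 0 }
  tens2 <- as_tensor(b)
  expect_equal(heaviness(tens2, tens2$genes, tens2$layers), 6)

  expect_error(heaviness(tens, "nope", "L1"), "unknown gene")
  expect_error(heaviness(tens, "g01", "L9"), "unknown layer")
})

test_that("module_density normalizes heaviness by the edge-slot count", {
  b <- array(0, c(3, 3, 2))
  for (k in 1:2) { b[, , k] <- 1; diag(b[, , k]) <- 0 }
  tens <- as_tensor(b)
  expect_equal(module_density(tens, tens$genes, tens$layers), 1.0)
  tens$a <- tens$a * 0.5
  expect_equal(module_density(tens, tens$genes, tens$layers), 0.5)

  empty <- as_tensor(array(0, c(3, 3, 1)))
  expect_equal(module_density(empty, c("g01", "g02"), "L1"), 0)
  expect_error(module_density(empty, "g01", "L1"), "two genes")
})

test_that("heaviness is additive over disjoint layer sets and monotone", {
  tens <- random_dense_tensor(6, 3, seed = 3)
  g <- tens$genes[1:4]
  expect_equal(
    heaviness(tens, g, c("L1", "L2")) + heaviness(tens, g, "L3"),
    heaviness(tens, g, c("L1", "L2", "L3"))
  )
  # adding a gene or a layer never decreases heaviness
  expect_gte(heaviness(tens, tens$genes[1:5], "L1"),
             heaviness(tens, tens$genes[1:4], "L1"))
  expect_gte(heaviness(tens, g, c("L1", "L2")), heaviness(tens, g, "L1"))
})

test_that("mine_rhs recovers a planted module exactly on a clean instance", {
  sim <- simulate_multilayer(
    30, 3, background_range = c(0.04, 0.06), edge_prob = 1,
    planted = list(list(size = 5, layers = 1:3, internal_range = c(0.9, 0.9))),
    seed = 21
  )
  fit <- mine_rhs(sim$tensor, miner_config(seed = 1, max_modules = 1))
  expect_length(fit$modules, 1L)
  m <- fit$modules[[1]]
  expect_identical(m$genes, sort(sim$truth$modules[[1]]$genes))
  expect_identical(m$layers, c("L1", "L2", "L3"))
  # reported heaviness and density are self-consistent
  expect_equal(m$heaviness, heaviness(sim$tensor, m$genes, m$layers))
  expect_equal(m$density, m$heaviness / (choose(5, 2) * 3))
})

test_that("mine_rhs returns an empty fit on structureless tensors", {
  zero <- as_tensor(array(0, c(6, 6, 2)))
  fit <- mine_rhs(zero, miner_config(seed = 1))
  expect_length(fit$modules, 0L)

  # below-threshold weights everywhere: no feasible pair
  weak <- as_tensor(array(0.2, c(5, 5, 2)) * as.numeric(!diag(5)))
  dim(weak$a) <- c(5, 5, 2)
  fit2 <- mine_rhs(weak, miner_config(density_threshold = 0.41, seed = 1))
  expect_length(fit2$modules, 0L)
})

test_that("two disjoint planted modules are mined in decreasing heaviness order", {
  sim <- simulate_multilayer(
    12, 2, background_range = c(0.02, 0.05), edge_prob = 0.3,
    planted = list(
      list(size = 5, layers = 1:2, internal_range = c(0.9, 1.0)),
      list(size = 4, layers = 1:2, internal_range = c(0.8, 0.9))
    ),
    seed = 8
  )
  fit <- mine_rhs(sim$tensor, miner_config(seed = 2))
  expect_gte(length(fit$modules), 2L)
  got <- lapply(fit$modules[1:2], `[[`, "genes")
  want <- lapply(sim$truth$modules, function(m) sort(m$genes))
  expect_identical(got[[1]], want[[1]])  # 5-gene module is heavier
  expect_identical(got[[2]], want[[2]])
  expect_gte(fit$modules[[1]]$heaviness, fit$modules[[2]]$heaviness)

  # the first module attains the exhaustive constrained optimum
  expect_equal(fit$modules[[1]]$heaviness,
               oracle_best_heaviness(sim$tensor, 0.41, 3))
})

test_that("mining is bit-deterministic given the seed", {
  tens <- random_dense_tensor(8, 3, seed = 17)
  f1 <- mine_rhs(tens, miner_config(seed = 5))
  f2 <- mine_rhs(tens, miner_config(seed = 5))
  f1$call <- f2$call <- NULL
  expect_identical(f1, f2)
})

test_that("miner modules reach >= 90% of the exhaustive optimum on small tensors", {
  # small-scale version of the oracle-equivalence property
  for (seed in 1:10) {
    tens <- random_dense_tensor(sample(5:8, 1), sample(2:3, 1), seed = 100 + seed)
    fit <- mine_rhs(tens, miner_config(seed = seed, max_modules = 1))
    h_mine <- if (length(fit$modules)) fit$modules[[1]]$heaviness else 0
    h_opt <- oracle_best_heaviness(tens, 0.41, 3)
    if (h_opt > 0) expect_gte(h_mine, 0.9 * h_opt)
    else expect_equal(h_mine, 0)
  }
})

test_that("every mined module satisfies its own invariants", {
  sim <- simulate_multilayer(
    40, 3, background_range = c(0.05, 0.2), edge_prob = 0.15,
    planted = list(
      list(size = 6, layers = 1:3, internal_range = c(0.7, 1.0)),
      list(size = 4, layers = 1:2, internal_range = c(0.75, 0.95))
    ),
    seed = 31
  )
  cfg <- miner_config(seed = 3)
  fit <- mine_rhs(sim$tensor, cfg)
  expect_gte(length(fit$modules), 1L)
  # recompute each module against the tensor minus previously masked modules
  a <- sim$tensor$a
  for (m in fit$modules) {
    tens_now <- sim$tensor
    tens_now$a <- a
    expect_gte(length(m$genes), cfg$min_size)
    expect_equal(m$heaviness, heaviness(tens_now, m$genes, m$layers))
    expect_equal(
      m$density,
      m$heaviness / (choose(length(m$genes), 2) * length(m$layers))
    )
    expect_gte(m$density, cfg$density_threshold)
    gi <- match(m$genes, tens_now$genes)
    li <- match(m$layers, tens_now$layers)
    a[gi, gi, li] <- 0
  }
})

test_that("module JSON-lines output round-trips", {
  sim <- simulate_multilayer(
    20, 2, background_range = c(0.02, 0.05), edge_prob = 0.2,
    planted = list(list(size = 4, layers = 1:2, internal_range = c(0.8, 1))),
    seed = 12
  )
  fit <- mine_rhs(sim$tensor, miner_config(seed = 1))
  jl <- tempfile(fileext = ".jsonl")
  write_modules(fit, jl, tsv_path = tempfile(fileext = ".tsv"))
  back <- read_modules(jl)
  expect_equal(length(back), length(fit$modules))
  expect_identical(back[[1]]$genes, fit$modules[[1]]$genes)
  expect_equal(back[[1]]$heaviness, fit$modules[[1]]$heaviness)
})

test_that("heaviness_scan is consistent with direct mining and flags empty scans", {
  sim <- simulate_multilayer(
    25, 2, background_range = c(0.03, 0.08), edge_prob = 0.2,
    planted = list(list(size = 5, layers = 1:2, internal_range = c(0.8, 1))),
    seed = 9
  )
  ann <- simulate_annotation(
    list(sim$truth$modules[[1]]$genes),
    n_background_genes = 200, seed = 4
  )
  drug_sets <- list(L1 = sim$truth$modules[[1]]$genes[1:3], L2 = c("g0001"))
  cfg <- miner_config(seed = 6)

  scan <- heaviness_scan(sim$tensor, 0.41, ann$annotation, drug_sets, cfg)
  direct <- mine_rhs(sim$tensor, cfg)
  expect_equal(scan$n_modules, length(direct$modules))
  fits <- attr(scan, "fits")
  expect_identical(
    lapply(fits[[1]]$modules, `[[`, "genes"),
    lapply(direct$modules, `[[`, "genes")
  )
  expect_true(scan$ratio_defined[1])
  expect_equal(scan$overlap_L1[1], 3L)

  # all-zero tensor: no modules, ratio undefined (NA), not zero
  zero <- as_tensor(array(0, c(5, 5, 2)))
  scan0 <- heaviness_scan(zero, c(0.3, 0.5), ann$annotation, drug_sets, cfg)
  expect_equal(scan0$n_modules, c(0L, 0L))
  expect_false(any(scan0$ratio_defined))
  expect_true(all(is.na(scan0$ratio)))
})

test_that("union of module genes shrinks as the threshold rises", {
  sim <- simulate_multilayer(
    40, 2, background_range = c(0.1, 0.4), edge_prob = 0.5,
    planted = list(list(size = 6, layers = 1:2, internal_range = c(0.8, 1))),
    seed = 14, allow_weak = TRUE
  )
  ann <- simulate_annotation(list(sim$truth$modules[[1]]$genes),
                             n_background_genes = 100, seed = 2)
  scan <- heaviness_scan(
    sim$tensor, c(0.3, 0.5, 0.7, 0.9), ann$annotation,
    list(L1 = sim$truth$modules[[1]]$genes), miner_config(seed = 3)
  )
  union_sizes <- vapply(attr(scan, "fits"), function(f) {
    length(unique(unlist(lapply(f$modules, `[[`, "genes"))))
  }, integer(1L))
  expect_true(all(diff(union_sizes) <= 0))
})
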
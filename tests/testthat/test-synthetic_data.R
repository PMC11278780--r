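models <- default_models()

test_that("simulation is reproducible under a fixed seed", {
  cfg <- simulation_config(n_strains = 30, seed = 7)
  a <- simulate_profiles(cfg)
  b <- simulate_profiles(cfg)
  expect_identical(unclass(a$profiles), unclass(b$profiles))
  expect_identical(a$truth$table, b$truth$table)
  # a different seed gives different draws
  c_ <- simulate_profiles(simulation_config(n_strains = 30, seed = 8))
  expect_false(identical(unclass(a$profiles), unclass(c_$profiles)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(simulate_profiles(simulation_config(n_strains = 5, seed = 3)))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("no-loss config reaches the full metabolite set everywhere", {
  cfg <- simulation_config(n_strains = 20, seed = 7,
                           cluster_presence_prob = c(PPZ = 1, EAS = 1,
                                                     IDT = 1, LOL = 1),
                           gene_dropout_prob = 0, allele_R_prob = 1)
  sim <- simulate_profiles(cfg)
  full <- unlist(lapply(models, model_products), use.names = FALSE)
  full <- setdiff(full, "PPZ-dione")  # R allele excludes the dR product
  for (id in rownames(sim$profiles))
    expect_setequal(unlist(sim$truth$producible[[id]]), full)
  expect_true(all(c("LTM-B", "LAH") %in%
                    unlist(sim$truth$producible[[1]])))
})

test_that("peramine-only config is ground-truth type 1, category I", {
  cfg <- simulation_config(n_strains = 20, seed = 7,
                           cluster_presence_prob = c(PPZ = 1, EAS = 0,
                                                     IDT = 0, LOL = 0),
                           gene_dropout_prob = 0, allele_R_prob = 1)
  sim <- simulate_profiles(cfg)
  expect_true(all(sim$truth$table$type == "1"))
  expect_true(all(sim$truth$table$category == "I"))
})

test_that("R and dR are never both present; idiomorphs are exclusive", {
  sim <- simulate_profiles(simulation_config(n_strains = 200, seed = 5,
                                             allele_R_prob = 0.5))
  m <- unclass(sim$profiles)
  expect_false(any(m[, "ppzA-R"] == "present" &
                     m[, "ppzA-dR"] == "present"))
  expect_false(any(m[, "mtAC"] == "present" & m[, "mtBA"] == "present"))
  expect_true(all(m[, "mtAC"] == "present" | m[, "mtBA"] == "present"))
})

test_that("engine recovers the stored ground truth strain for strain", {
  cfg <- simulation_config(n_strains = 500, seed = 1,
                           gene_dropout_prob = 0.15)
  sim <- simulate_profiles(cfg)
  res <- suppressWarnings(run_pipeline(sim$profiles, models))
  expect_identical(length(res), 500L)
  for (i in seq_along(res)) {
    r <- res[[i]]
    t <- sim$truth$table[i, ]
    expect_identical(r$chem_type, t$type, info = r$strain_id)
    expect_identical(r$safety_category, t$category, info = r$strain_id)
    expect_identical(r$ppz_allele, t$allele, info = r$strain_id)
    expect_identical(paste(r$producible, collapse = ","), t$producible,
                     info = r$strain_id)
  }
})

test_that("recovery is exact at zero dropout for any cluster retention", {
  for (seed in 1:3) {
    cfg <- simulation_config(n_strains = 50, seed = seed,
                             cluster_presence_prob = c(PPZ = 0.7, EAS = 0.5,
                                                       IDT = 0.5, LOL = 0.3),
                             gene_dropout_prob = 0)
    sim <- simulate_profiles(cfg)
    res <- suppressWarnings(run_pipeline(sim$profiles))
    agree <- vapply(seq_along(res), function(i)
      identical(res[[i]]$chem_type, sim$truth$table$type[i]) &&
        identical(res[[i]]$safety_category, sim$truth$table$category[i]),
      logical(1))
    expect_identical(mean(agree), 1, info = paste("seed", seed))
  }
})

test_that("masking to unknown shrinks strict-policy producible sets monotonically", {
  sim <- simulate_profiles(simulation_config(n_strains = 40, seed = 11))
  masked <- mask_unknowns(sim$profiles, 0.3, seed = 2)
  expect_identical(unclass(mask_unknowns(sim$profiles, 0)),
                   unclass(sim$profiles))
  all_unknown <- mask_unknowns(sim$profiles, 1, seed = 2)
  expect_true(all(unclass(all_unknown) == "unknown"))
  for (s in rownames(sim$profiles)) {
    for (m in models) {
      base <- suppressWarnings(
        producible_metabolites(profile_calls(sim$profiles, s), m, "strict"))
      shr <- suppressWarnings(
        producible_metabolites(profile_calls(masked, s), m, "strict"))
      expect_true(all(shr %in% base), info = paste(s, m$name))
      none <- suppressWarnings(
        producible_metabolites(profile_calls(all_unknown, s), m, "strict"))
      expect_identical(none, character(0))
    }
  }
  # deterministic under a fixed seed
  expect_identical(unclass(mask_unknowns(sim$profiles, 0.3, seed = 2)),
                   unclass(masked))
})

test_that("invalid configurations are refused", {
  expect_error(simulation_config(n_strains = 0),
               class = "chemotypeR_validation_error")
  expect_error(simulation_config(gene_dropout_prob = 1.2),
               class = "chemotypeR_validation_error")
  expect_error(simulation_config(cluster_presence_prob = c(PPZ = 1)),
               class = "chemotypeR_validation_error")
  expect_error(mask_unknowns(fixture_profiles(), -0.1),
               class = "chemotypeR_validation_error")
})
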
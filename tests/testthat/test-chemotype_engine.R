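models <- default_models()

test_that("producibility matches the study strains' cluster genotypes", {
  pr <- fixture_profiles()
  # 11-gene EAS core without the lpsC/easO/easP terminal trio: ergot set
  # stops at ergovaline
  ke1 <- profile_calls(pr, "KE1")
  expect_setequal(producible_metabolites(ke1, models$EAS),
                  c("CC", "D-LC", "ERV"))
  # idtP missing: paxilline gate closed, paspaline only
  ga2 <- profile_calls(pr, "GA2")
  expect_setequal(producible_metabolites(ga2, models$IDT), "PAS")
  # whole EAS cluster absent: no ergot alkaloid at all
  le6 <- profile_calls(pr, "LE6")
  expect_identical(producible_metabolites(le6, models$EAS), character(0))
  # lolC alone never opens the five-gene AcAP gate
  for (s in rownames(pr))
    expect_identical(producible_metabolites(profile_calls(pr, s),
                                            models$LOL),
                     character(0), info = s)
})

test_that("an all-present profile reaches every metabolite in every model", {
  calls <- make_calls(default = "present")
  for (m in models)
    expect_setequal(producible_metabolites(calls, m), model_products(m))
})

test_that("unknown calls follow the policy and raise a warning", {
  calls <- make_calls(present = model_markers(models$IDT),
                      unknown = "idtP")
  expect_warning(strict <- producible_metabolites(calls, models$IDT,
                                                  "strict"),
                 "idtP")
  expect_setequal(strict, "PAS")
  expect_warning(opt <- producible_metabolites(calls, models$IDT,
                                               "optimistic"),
                 "idtP")
  expect_setequal(opt, model_products(models$IDT))
})

test_that("a profile missing a model marker is refused with the marker named", {
  calls <- make_calls()[setdiff(all_markers, "idtS")]
  err <- expect_error(producible_metabolites(calls, models$IDT),
                      class = "chemotypeR_validation_error")
  expect_match(conditionMessage(err), "idtS")
})

test_that("ppzA allele calls cover all four outcomes", {
  pr <- fixture_profiles()
  expect_identical(call_ppz_allele(profile_calls(pr, "ADX8")), "ppzA-1")
  expect_identical(call_ppz_allele(profile_calls(pr, "FC1")), "ppzA-2")
  expect_identical(call_ppz_allele(make_calls()), "none")
  expect_warning(
    con <- call_ppz_allele(make_calls(present = c("ppzA-R", "ppzA-dR"))),
    "conflict")
  expect_identical(con, "conflict")
})

test_that("mating-type calls cover all four outcomes", {
  pr <- fixture_profiles()
  expect_identical(call_mating_type(profile_calls(pr, "LB1")), "A")
  expect_identical(call_mating_type(make_calls(present = "mtBA")), "B")
  expect_identical(call_mating_type(make_calls()), "undetermined")
  expect_warning(
    con <- call_mating_type(make_calls(present = c("mtAC", "mtBA"))),
    "conflict")
  expect_identical(con, "conflict")
})

test_that("pattern codes are derived from raw calls, not copied from a summary", {
  pr <- fixture_profiles()
  expect_identical(assign_pattern_codes(profile_calls(pr, "LE6")),
                   c(PPZ = "A", EAS = "B", IDT = "A", LOL = "A"))
  expect_identical(assign_pattern_codes(profile_calls(pr, "KE1")),
                   c(PPZ = "B", EAS = "A", IDT = "B", LOL = "A"))
  expect_identical(assign_pattern_codes(profile_calls(pr, "FC1")),
                   c(PPZ = "B", EAS = "A", IDT = "C", LOL = "A"))
  # idtP absent puts the GA strains in code C by the code definitions,
  # whatever a printed summary may say
  expect_identical(assign_pattern_codes(profile_calls(pr, "GA2"))[["IDT"]],
                   "C")
  # unmatched signatures get X with a warning
  odd <- make_calls(present = "idtP")
  warns <- capture_warnings(codes <- assign_pattern_codes(odd))
  expect_true(any(grepl("IDT matches no defined pattern code", warns)))
  expect_identical(codes[["IDT"]], "X")
  # EAS still matches B (whole cluster absent); the rest match nothing
  expect_identical(unname(codes), c("X", "B", "X", "X"))
})

test_that("type assignment reproduces the four chemotype archetypes", {
  pr <- fixture_profiles()
  type_of <- function(s) {
    calls <- profile_calls(pr, s)
    assign_type(lapply(models, function(m)
      producible_metabolites(calls, m)))
  }
  expect_identical(type_of("LE1"), "1")
  expect_identical(type_of("AD3"), "2")
  expect_identical(type_of("GA2"), "3")
  expect_identical(type_of("KEM4"), "4")
  # EAS products without any IDT match no archetype
  expect_warning(
    u <- assign_type(list(PPZ = character(0), EAS = c("CC", "D-LC", "ERV"),
                          IDT = character(0))),
    "no defined type")
  expect_identical(u, "unclassified")
  expect_warning(
    u0 <- assign_type(list(PPZ = character(0), EAS = character(0),
                           IDT = character(0))),
    "no defined type")
  expect_identical(u0, "unclassified")
})

test_that("safety category is exactly toxic-product intersection emptiness", {
  pr <- fixture_profiles()
  cat_of <- function(s) {
    calls <- profile_calls(pr, s)
    assign_safety_category(unlist(lapply(models, function(m)
      producible_metabolites(calls, m))), models)
  }
  expect_identical(cat_of("LE7"), "I")
  expect_identical(cat_of("LB1"), "II")
  # paspaline alone is already toxic
  expect_identical(assign_safety_category("PAS", models), "II")
  # peramine and lolines are insect-active but livestock-safe
  expect_identical(assign_safety_category(c("PER", "AcAP", "NFL"), models),
                   "I")
  expect_identical(assign_safety_category(character(0), models), "I")
})

test_that("full pipeline on the bundled strains gives the study's partition", {
  res <- run_pipeline(fixture_profiles())
  s <- attr(res, "summary")
  expect_identical(as.integer(s$type_counts[c("1", "2", "3", "4")]),
                   c(4L, 6L, 5L, 5L))
  expect_identical(as.integer(s$category_counts), c(4L, 16L))
  expect_identical(as.integer(s$mating_counts[["A"]]), 20L)
  # category I strains have no warnings pending and empty toxic overlap
  toxic <- unique(unlist(lapply(models, `[[`, "toxic_products")))
  for (r in res)
    if (r$safety_category == "I")
      expect_length(intersect(r$producible, toxic), 0)
  # empty input: empty results, zero summary
  empty <- run_pipeline(fixture_profiles()[0, , drop = FALSE])
  expect_length(empty, 0)
  expect_identical(sum(attr(empty, "summary")$type_counts), 0L)
})

test_that("terminal products are the producible frontier", {
  res <- run_pipeline(fixture_profiles())
  for (r in res) {
    expect_true(all(r$terminal_products %in% r$producible))
    # KE1-like strains: ergot frontier is ERV, indole-diterpene TDK
    if (r$strain_id == "KE1")
      expect_setequal(r$terminal_products, c("PPZ-dione", "ERV", "TDK"))
    if (r$strain_id == "LE6")
      expect_setequal(r$terminal_products, "PER")
  }
})

test_that("monotonicity: flipping absent to present never loses a metabolite", {
  set.seed(101)
  for (rep in 1:40) {
    calls <- random_calls(p = c(present = 0.5, absent = 0.5, unknown = 0))
    for (m in models) {
      base <- producible_metabolites(calls, m)
      absent <- intersect(model_markers(m),
                          names(calls)[calls == "absent"])
      if (!length(absent)) next
      flip <- sample(absent, 1)
      calls2 <- calls
      calls2[flip] <- "present"
      expect_true(all(base %in% producible_metabolites(calls2, m)),
                  info = sprintf("%s flip %s", m$name, flip))
    }
  }
})

test_that("knockout soundness: removing a gate gene removes the product and its descendants", {
  full <- make_calls(default = "present")
  for (m in models) {
    steps <- setNames(m$steps, model_products(m))
    # descendants through the precursor chain
    desc <- function(x) {
      kids <- names(steps)[vapply(steps, function(s)
        !is.null(s$precursor) && s$precursor == x, logical(1))]
      unique(c(kids, unlist(lapply(kids, desc))))
    }
    for (p in names(steps)) {
      for (g in steps[[p]]$required_genes) {
        # skip genes shared with another step's gate (not a unique gate)
        others <- setdiff(names(steps), c(p, desc(p)))
        if (g %in% unlist(lapply(steps[others], `[[`, "required_genes")))
          next
        ko <- full
        ko[g] <- "absent"
        got <- producible_metabolites(ko, m)
        expect_false(p %in% got, info = sprintf("%s: %s ko %s", m$name, p, g))
        expect_true(all(!desc(p) %in% got),
                    info = sprintf("%s: descendants of %s after ko %s",
                                   m$name, p, g))
      }
    }
  }
})

test_that("topological engine agrees with the fixed-point oracle on random profiles", {
  set.seed(2024)
  for (rep in 1:250) {
    calls <- random_calls()
    for (m in models) {
      for (policy in c("strict", "optimistic")) {
        eng <- suppressWarnings(producible_metabolites(calls, m, policy))
        ora <- producible_fixed_point(calls, m, policy)
        expect_identical(eng, ora,
                         info = sprintf("%s/%s rep %d", m$name, policy, rep))
      }
    }
  }
})
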
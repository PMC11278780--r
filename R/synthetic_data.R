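# Seeded simulator of marker profiles with known ground-truth chemotypes,
# plus the fixed-point producibility oracle used to compute that truth
# independently of the topological-order engine.

#' Fixed-point producibility oracle
#'
#' Independent reference implementation of pathway reachability: start from
#' the empty set and repeatedly add any step whose gene gate is satisfied
#' and whose precursor (if any) is already in the set, until nothing
#' changes.  Shares no code with \code{\link{producible_metabolites}} (which
#' evaluates once in topological order); the two must agree on every input,
#' and the test suite checks that they do.
#'
#' @param calls named tri-state call vector.
#' @param model a \code{\link{pathway_model}}.
#' @param unknown_policy \code{"strict"} or \code{"optimistic"}.
#' @return Character vector of producible metabolite ids, in step order.
#' @export
producible_fixed_point <- function(calls, model,
                                   unknown_policy = c("strict", "optimistic")) {
  unknown_policy <- match.arg(unknown_policy)
  present <- calls == "present"
  if (unknown_policy == "optimistic") present <- present | calls == "unknown"
  producible <- character(0)
  repeat {
    added <- FALSE
    for (s in model$steps) {
      if (s$product %in% producible) next
      if (!all(s$required_genes %in% names(calls)[present])) next
      if (!is.null(s$precursor) && !(s$precursor %in% producible)) next
      producible <- c(producible, s$product)
      added <- TRUE
    }
    if (!added) break
  }
  intersect(model_products(model), producible)
}

#' Simulation configuration
#'
#' Parameters of the two-level loss model the simulator uses, mirroring the
#' two modes of gene loss seen in real marker surveys: whole-cluster
#' absence (a strain simply lacks the cluster) and per-gene dropout within
#' a retained cluster (single-gene losses such as idtP).
#'
#' @param n_strains number of strains to simulate.
#' @param seed integer seed; identical configs give byte-identical output.
#' @param cluster_presence_prob named probabilities that each cluster (PPZ,
#'   EAS, IDT, LOL) is retained.  Defaults are the retention fractions
#'   observed in the bundled 20-strain study (PPZ and LOL in all strains,
#'   EAS and IDT in 16/20).
#' @param gene_dropout_prob per-gene loss probability within a retained
#'   cluster (default 0.15).
#' @param allele_R_prob probability that a PPZ-bearing strain carries the
#'   full-length R allele rather than dR (default 0.5, the observed 10/20
#'   split); the two are never both present.
#' @param mating_A_prob probability of mating type A (mtAC); mtAC and mtBA
#'   are drawn mutually exclusively.  Default 1, as in the bundled study
#'   where all strains are type A.
#' @param unknown_prob probability that a call is masked to unknown after
#'   generation (default 0).
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_strains = 20L, seed = 1L,
                              cluster_presence_prob = c(PPZ = 1, EAS = 0.8,
                                                        IDT = 0.8, LOL = 1),
                              gene_dropout_prob = 0.15,
                              allele_R_prob = 0.5,
                              mating_A_prob = 1,
                              unknown_prob = 0) {
  if (!is.numeric(n_strains) || length(n_strains) != 1L || n_strains < 1 ||
      n_strains != floor(n_strains))
    abort_validation("n_strains must be a positive integer")
  probs <- c(cluster_presence_prob, gene_dropout_prob, allele_R_prob,
             mating_A_prob, unknown_prob)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    abort_validation("all probabilities must lie in [0, 1]")
  miss <- setdiff(c("PPZ", "EAS", "IDT", "LOL"),
                  names(cluster_presence_prob))
  if (length(miss))
    abort_validation(sprintf("cluster_presence_prob missing: %s",
                             paste(miss, collapse = ", ")))
  structure(list(n_strains = as.integer(n_strains), seed = as.integer(seed),
                 cluster_presence_prob = cluster_presence_prob,
                 gene_dropout_prob = gene_dropout_prob,
                 allele_R_prob = allele_R_prob,
                 mating_A_prob = mating_A_prob,
                 unknown_prob = unknown_prob),
            class = "simulation_config")
}

# Run expr with a private RNG stream so simulation never disturbs (or
# depends on) the caller's random state.
with_private_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(list = ".Random.seed",
                                   envir = globalenv())))
  set.seed(seed)
  expr
}

# Classify a producible-set list into type/category without touching the
# engine's classifier (kept separate so the simulator's ground truth is an
# independent route end to end).
truth_classify <- function(producible_by_model, models) {
  per <- "PER" %in% producible_by_model$PPZ
  eas <- sort(producible_by_model$EAS)
  idt <- sort(producible_by_model$IDT)
  type <-
    if (per && !length(eas) && !length(idt)) "1"
    else if (per && identical(eas, sort(c("CC", "D-LC", "ERV"))) &&
             identical(idt, sort(c("PAS", "PAX", "TDK")))) "2"
    else if (!per && identical(eas, sort(c("CC", "D-LC", "ERV"))) &&
             identical(idt, "PAS")) "3"
    else if (!per && identical(eas, sort(c("CC", "D-LC", "ERV"))) &&
             identical(idt, sort(c("PAS", "PAX", "TDK")))) "4"
    else "unclassified"
  toxic <- unique(unlist(lapply(models, `[[`, "toxic_products")))
  category <- if (length(intersect(unlist(producible_by_model), toxic)))
    "II" else "I"
  list(type = type, category = category)
}

#' Simulate marker profiles with known ground truth
#'
#' Draws per-strain profiles under the two-level loss model of
#' \code{\link{simulation_config}}: each cluster is retained with its
#' probability; within a retained cluster every gene survives dropout
#' independently; the ppzA R/dR pair and the mtAC/mtBA idiomorphs are drawn
#' mutually exclusively.  Ground-truth producible sets, allele, type and
#' category are computed at generation time with the fixed-point oracle
#' (\code{\link{producible_fixed_point}}), independent of the inference
#' engine.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param models pathway models (default \code{\link{default_models}()}).
#' @return A list with elements \code{profiles} (a \code{gene_profiles}
#'   matrix, masked to unknown where \code{unknown_prob > 0}) and
#'   \code{truth} (list: \code{table} data frame with strain, allele,
#'   mating type, type, category; \code{producible} named list of per-model
#'   sets; \code{retained} and \code{dropped} per-strain bookkeeping;
#'   \code{config}).  Truth always refers to the unmasked calls.
#' @export
#' @examples
#' sim <- simulate_profiles(simulation_config(n_strains = 5, seed = 42))
#' sim$truth$table
simulate_profiles <- function(config, models = default_models()) {
  stopifnot(inherits(config, "simulation_config"))
  registry <- marker_registry()
  markers <- registry$id
  cluster_of <- stats::setNames(registry$cluster, registry$id)
  with_private_rng(config$seed, {
    n <- config$n_strains
    ids <- sprintf("SIM%03d", seq_len(n))
    calls <- matrix("absent", nrow = n, ncol = length(markers),
                    dimnames = list(ids, markers))
    retained <- vector("list", n); names(retained) <- ids
    dropped <- vector("list", n); names(dropped) <- ids
    delta <- config$gene_dropout_prob
    for (i in seq_len(n)) {
      pi_cl <- config$cluster_presence_prob
      keep <- names(pi_cl)[stats::runif(length(pi_cl)) < pi_cl]
      # mating type: exactly one idiomorph
      mt_a <- stats::runif(1) < config$mating_A_prob
      calls[i, if (mt_a) "mtAC" else "mtBA"] <- "present"
      drop_i <- character(0)
      for (cl in keep) {
        genes <- markers[cluster_of[markers] == cl]
        if (cl == "PPZ") {
          # exclusive allele choice, then dropout on every segment
          allele <- if (stats::runif(1) < config$allele_R_prob)
            "ppzA-R" else "ppzA-dR"
          genes <- c(setdiff(genes, c("ppzA-R", "ppzA-dR")), allele)
        }
        surv <- genes[stats::runif(length(genes)) >= delta]
        drop_i <- c(drop_i, setdiff(genes, surv))
        calls[i, surv] <- "present"
      }
      retained[[i]] <- keep
      dropped[[i]] <- drop_i
    }
    profiles <- structure(calls, class = "gene_profiles",
                          host = stats::setNames(character(0), character(0)),
                          location = stats::setNames(character(0),
                                                     character(0)))
    producible <- lapply(ids, function(id) {
      cl <- stats::setNames(calls[id, ], colnames(calls))
      lapply(models, function(m) producible_fixed_point(cl, m))
    })
    names(producible) <- ids
    rows <- lapply(ids, function(id) {
      cls <- truth_classify(producible[[id]], models)
      r <- calls[id, "ppzA-R"] == "present"
      dr <- calls[id, "ppzA-dR"] == "present"
      data.frame(
        strain = id,
        allele = if (r && dr) "conflict" else if (r) "ppzA-1"
                 else if (dr) "ppzA-2" else "none",
        mating_type = if (calls[id, "mtAC"] == "present") "A" else "B",
        type = cls$type,
        category = cls$category,
        producible = paste(unlist(producible[[id]]), collapse = ","),
        stringsAsFactors = FALSE)
    })
    truth <- list(table = do.call(rbind, rows),
                  producible = producible,
                  retained = retained,
                  dropped = dropped,
                  config = config)
    rownames(truth$table) <- NULL
    if (config$unknown_prob > 0)
      profiles <- mask_unknowns(profiles, config$unknown_prob,
                                seed = config$seed + 1L)
    list(profiles = profiles, truth = truth)
  })
}

#' Mask calls to unknown at random
#'
#' Independently replaces each call with \code{"unknown"} with the given
#' probability.  Under the strict unknown policy, masking can only shrink
#' producible sets, never grow them.
#'
#' @param profiles a \code{gene_profiles} object.
#' @param prob masking probability in [0, 1].
#' @param seed integer seed.
#' @return The masked \code{gene_profiles}.
#' @export
mask_unknowns <- function(profiles, prob, seed = 1L) {
  if (!is.numeric(prob) || length(prob) != 1L || prob < 0 || prob > 1)
    abort_validation("prob must lie in [0, 1]")
  if (prob == 0) return(profiles)
  m <- unclass(profiles)
  with_private_rng(seed, {
    mask <- matrix(stats::runif(length(m)) < prob, nrow = nrow(m))
    m[mask] <- "unknown"
  })
  structure(m, class = "gene_profiles",
            host = attr(profiles, "host"),
            location = attr(profiles, "location"))
}
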
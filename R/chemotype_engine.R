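# Core inference: boolean pathway reachability over the gene-gated DAGs,
# allele and mating-type calls, Table-style pattern codes, chemotype type
# (1-4) and livestock-safety category (I/II).

# Resolve tri-state calls to logical presence under a policy.  Unknown
# counts as absent under "strict" (conservative for safety screening) and
# as present under "optimistic" (sensitivity analysis).
resolve_presence <- function(calls, unknown_policy = c("strict", "optimistic")) {
  unknown_policy <- match.arg(unknown_policy)
  out <- calls == "present"
  if (unknown_policy == "optimistic")
    out <- out | calls == "unknown"
  out
}

#' Producible metabolites for one strain
#'
#' Evaluates a pathway model against one strain's marker calls: a metabolite
#' is producible iff every gene in its step's gate is present and its
#' precursor (if any) is itself producible.  Steps are evaluated in
#' topological order, so the result is deterministic and computed in one
#' pass.
#'
#' @param calls named character vector of tri-state calls
#'   (\code{"present"}/\code{"absent"}/\code{"unknown"}) covering at least
#'   the markers the model's gates reference, or a single-row
#'   \code{gene_profiles} object.
#' @param model a \code{\link{pathway_model}}.
#' @param unknown_policy how unknown calls are resolved: \code{"strict"}
#'   (treated as absent; default) or \code{"optimistic"} (treated as
#'   present).  Either way a warning reports which unknown markers were
#'   consulted.
#' @return Character vector of producible metabolite ids, in step order.
#' @export
#' @examples
#' m <- default_models()$IDT
#' calls <- setNames(rep("present", 11), model_markers(m))
#' producible_metabolites(calls, m)
producible_metabolites <- function(calls, model,
                                   unknown_policy = c("strict", "optimistic")) {
  unknown_policy <- match.arg(unknown_policy)
  if (inherits(calls, "gene_profiles")) {
    stopifnot(nrow(calls) == 1L)
    calls <- profile_calls(calls, rownames(calls))
  }
  needed <- model_markers(model)
  missing <- setdiff(needed, names(calls))
  if (length(missing))
    abort_validation(sprintf(
      "profile lacks marker(s) required by model %s: %s",
      model$name, paste(missing, collapse = ", ")))
  if (is.null(model$topo_order))
    abort_validation(sprintf("model %s has no topological order (cyclic?)",
                             model$name))
  unk <- intersect(needed, names(calls)[calls == "unknown"])
  if (length(unk))
    warning(sprintf("model %s: unknown call(s) treated as %s: %s",
                    model$name,
                    if (unknown_policy == "strict") "absent" else "present",
                    paste(unk, collapse = ", ")), call. = FALSE)
  present <- resolve_presence(calls, unknown_policy)
  steps <- model$steps
  names(steps) <- vapply(steps, `[[`, character(1), "product")
  producible <- character(0)
  for (p in model$topo_order) {
    s <- steps[[p]]
    gates_ok <- all(present[s$required_genes])
    prec_ok <- is.null(s$precursor) || s$precursor %in% producible
    if (gates_ok && prec_ok) producible <- c(producible, p)
  }
  # report in declaration (pathway) order
  intersect(model_products(model), producible)
}

#' Call the ppzA allele from the R/dR segment pair
#'
#' The peramine synthetase gene occurs as two mutually exclusive alleles:
#' full-length with the reductase (R) domain (allele ppzA-1, peramine
#' producer) or with R deleted (dR; allele ppzA-2, producing
#' pyrrolopyrazine-1,4-diones instead).
#'
#' @param calls named tri-state call vector with entries \code{"ppzA-R"}
#'   and \code{"ppzA-dR"}.
#' @return One of \code{"ppzA-1"}, \code{"ppzA-2"}, \code{"none"},
#'   \code{"conflict"} (the last with a warning).
#' @export
call_ppz_allele <- function(calls) {
  if (inherits(calls, "gene_profiles")) {
    stopifnot(nrow(calls) == 1L)
    calls <- profile_calls(calls, rownames(calls))
  }
  if (!all(c("ppzA-R", "ppzA-dR") %in% names(calls)))
    abort_validation("calls must include ppzA-R and ppzA-dR")
  r <- calls[["ppzA-R"]] == "present"
  dr <- calls[["ppzA-dR"]] == "present"
  if (r && dr) {
    warning("both ppzA-R and ppzA-dR amplified: allele conflict",
            call. = FALSE)
    return("conflict")
  }
  if (r) "ppzA-1" else if (dr) "ppzA-2" else "none"
}

#' Call the mating type from the idiomorph markers
#'
#' @param calls named tri-state call vector with entries \code{"mtAC"} and
#'   \code{"mtBA"}.
#' @return One of \code{"A"}, \code{"B"}, \code{"undetermined"},
#'   \code{"conflict"} (the last with a warning).
#' @export
call_mating_type <- function(calls) {
  if (inherits(calls, "gene_profiles")) {
    stopifnot(nrow(calls) == 1L)
    calls <- profile_calls(calls, rownames(calls))
  }
  if (!all(c("mtAC", "mtBA") %in% names(calls)))
    abort_validation("calls must include mtAC and mtBA")
  ac <- calls[["mtAC"]] == "present"
  ba <- calls[["mtBA"]] == "present"
  if (ac && ba) {
    warning("both mtAC and mtBA amplified: mating-type conflict",
            call. = FALSE)
    return("conflict")
  }
  if (ac) "A" else if (ba) "B" else "undetermined"
}

# Per-cluster pattern-code predicates, as used in chemotype summaries:
# each letter names a fixed presence/absence signature of the cluster.
.PATTERN_CODES <- list(
  PPZ = list(
    A = function(p) p[["ppzA-R"]] && !p[["ppzA-dR"]],
    B = function(p) p[["ppzA-dR"]] && !p[["ppzA-R"]]
  ),
  EAS = list(
    A = function(p) all(p[.EAS_CORE11]),
    B = function(p) !any(p[.EAS_GENES])
  ),
  IDT = list(
    A = function(p) !any(p[.IDT_GENES]),
    B = function(p) all(p[c(.IDT_CORE5, "idtP", "idtQ", "idtF", "idtK")]) &&
      !any(p[c("idtE", "idtJ")]),
    C = function(p) all(p[c(.IDT_CORE5, "idtQ", "idtF", "idtK")]) &&
      !any(p[c("idtP", "idtE", "idtJ")])
  ),
  LOL = list(
    A = function(p) p[["lolC"]] && !any(p[setdiff(.LOL_GENES, "lolC")])
  )
)

#' Assign per-cluster pattern codes
#'
#' Derives a letter code per cluster from the raw calls: for PPZ, A = R
#' segment without dR, B = dR without R; for EAS, A = the 11-gene core all
#' present, B = the whole cluster absent; for IDT, A = cluster absent, B =
#' the nine genes through idtK present with idtE/idtJ absent, C = the same
#' but also lacking idtP; for LOL, A = lolC alone.  A profile matching no
#' defined letter gets \code{"X"} with a warning.  Codes are always derived
#' from the calls themselves, never copied from a published summary.
#'
#' @param calls named tri-state call vector covering all four clusters, or a
#'   single-row \code{gene_profiles}.
#' @param unknown_policy see \code{\link{producible_metabolites}}.
#' @return Named character vector of codes for PPZ, EAS, IDT, LOL.
#' @export
assign_pattern_codes <- function(calls,
                                 unknown_policy = c("strict", "optimistic")) {
  unknown_policy <- match.arg(unknown_policy)
  if (inherits(calls, "gene_profiles")) {
    stopifnot(nrow(calls) == 1L)
    calls <- profile_calls(calls, rownames(calls))
  }
  needed <- c(.PPZ_DOMAINS, .EAS_GENES, .IDT_GENES, .LOL_GENES)
  missing <- setdiff(needed, names(calls))
  if (length(missing))
    abort_validation(sprintf("profile lacks marker(s): %s",
                             paste(missing, collapse = ", ")))
  p <- resolve_presence(calls, unknown_policy)
  out <- character(0)
  for (cl in names(.PATTERN_CODES)) {
    code <- "X"
    for (letter in names(.PATTERN_CODES[[cl]]))
      if (isTRUE(.PATTERN_CODES[[cl]][[letter]](p))) { code <- letter; break }
    if (code == "X")
      warning(sprintf("cluster %s matches no defined pattern code", cl),
              call. = FALSE)
    out[cl] <- code
  }
  out
}

# Per-type producible-set signatures over the EAS and IDT pathways plus the
# peramine flag.  Types are defined over producible sets, not pattern-code
# tuples, so single-gene losses (e.g. idtP) classify by their metabolic
# consequence.
.TYPE_RULES <- list(
  `1` = list(per = TRUE,  eas = character(0),            idt = character(0)),
  `2` = list(per = TRUE,  eas = c("CC", "D-LC", "ERV"),  idt = c("PAS", "PAX", "TDK")),
  `3` = list(per = FALSE, eas = c("CC", "D-LC", "ERV"),  idt = "PAS"),
  `4` = list(per = FALSE, eas = c("CC", "D-LC", "ERV"),  idt = c("PAS", "PAX", "TDK"))
)

#' Assign the chemotype type (1-4)
#'
#' Type 1: peramine producible, no ergot or indole-diterpene product.
#' Type 2: peramine plus ergot set \{CC, D-LC, ERV\} and indole-diterpene
#' set \{PAS, PAX, TDK\}.  Type 3: no peramine, ergot set \{CC, D-LC, ERV\}
#' and paspaline only.  Type 4: as type 3 but with \{PAS, PAX, TDK\}.
#' Any other combination is \code{"unclassified"} (with a warning).
#'
#' @param producible_by_model named list of producible metabolite id vectors,
#'   one per pathway model (must include \code{PPZ}, \code{EAS},
#'   \code{IDT}).
#' @return \code{"1"}, \code{"2"}, \code{"3"}, \code{"4"} or
#'   \code{"unclassified"}.
#' @export
assign_type <- function(producible_by_model) {
  stopifnot(all(c("PPZ", "EAS", "IDT") %in% names(producible_by_model)))
  per <- "PER" %in% producible_by_model$PPZ
  eas <- producible_by_model$EAS
  idt <- producible_by_model$IDT
  for (ty in names(.TYPE_RULES)) {
    r <- .TYPE_RULES[[ty]]
    if (per == r$per && setequal(eas, r$eas) && setequal(idt, r$idt))
      return(ty)
  }
  warning(sprintf(
    "producible sets match no defined type (peramine=%s, EAS={%s}, IDT={%s})",
    per, paste(eas, collapse = ","), paste(idt, collapse = ",")),
    call. = FALSE)
  "unclassified"
}

#' Assign the livestock-safety category
#'
#' Category I: the strain can produce no metabolite flagged toxic in any
#' model (animal-safe; insect-active alkaloids such as peramine and lolines
#' do not count).  Category II: at least one toxic ergot or
#' indole-diterpene product is producible.
#'
#' @param producible character vector of all producible metabolite ids.
#' @param models list of pathway models supplying \code{toxic_products}.
#' @return \code{"I"} or \code{"II"}.
#' @export
assign_safety_category <- function(producible, models) {
  toxic <- unique(unlist(lapply(models, `[[`, "toxic_products")))
  if (length(intersect(producible, toxic))) "II" else "I"
}

# Producible metabolites with no producible successor step.
terminal_of <- function(producible_by_model, models) {
  unlist(lapply(names(models), function(nm) {
    m <- models[[nm]]
    prod <- producible_by_model[[nm]]
    succ_prec <- vapply(m$steps, function(s)
      if (is.null(s$precursor)) NA_character_ else s$precursor, character(1))
    has_succ <- vapply(prod, function(p)
      any(!is.na(succ_prec) & succ_prec == p &
            model_products(m) %in% prod), logical(1))
    prod[!has_succ]
  }), use.names = FALSE)
}

#' Run the full chemotype pipeline
#'
#' For every strain: computes the producible metabolite set of each pathway
#' model, calls the ppzA allele and mating type, derives pattern codes,
#' assigns the chemotype type and safety category, and collects any
#' warnings raised along the way into the per-strain result.
#'
#' @param profiles a \code{gene_profiles} object.
#' @param models named list of pathway models
#'   (default \code{\link{default_models}()}).
#' @param unknown_policy \code{"strict"} (default) or \code{"optimistic"}.
#' @return An object of class \code{chemotype_results}: a list with one
#'   \code{chemotype_result} per strain (input order) and a \code{summary}
#'   attribute with counts per type, category and mating type.
#' @export
#' @examples
#' pr <- read_profiles(chemotype_example("elymus_profiles.tsv"))
#' res <- run_pipeline(pr)
#' attr(res, "summary")$type_counts
run_pipeline <- function(profiles, models = default_models(),
                         unknown_policy = c("strict", "optimistic")) {
  unknown_policy <- match.arg(unknown_policy)
  strains <- rownames(profiles)
  results <- vector("list", length(strains))
  names(results) <- strains
  for (i in seq_along(strains)) {
    calls <- profile_calls(profiles, strains[i])
    warns <- character(0)
    collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    producible_by_model <- collect(lapply(models, function(m)
      producible_metabolites(calls, m, unknown_policy)))
    allele <- collect(call_ppz_allele(calls))
    mt <- collect(call_mating_type(calls))
    codes <- collect(assign_pattern_codes(calls, unknown_policy))
    ty <- collect(assign_type(producible_by_model))
    producible <- unlist(producible_by_model, use.names = FALSE)
    cat_ <- assign_safety_category(producible, models)
    if (!any(resolve_presence(calls, unknown_policy)))
      warns <- c(warns, "no marker present for any cluster")
    results[[i]] <- structure(list(
      strain_id = strains[i],
      producible = producible,
      producible_by_model = producible_by_model,
      terminal_products = terminal_of(producible_by_model, models),
      ppz_allele = allele,
      mating_type = mt,
      pattern_codes = codes,
      chem_type = ty,
      safety_category = cat_,
      warnings = unique(warns)
    ), class = "chemotype_result")
  }
  summary <- list(
    n = length(results),
    type_counts = table(factor(
      vapply(results, `[[`, character(1), "chem_type"),
      levels = c("1", "2", "3", "4", "unclassified"))),
    category_counts = table(factor(
      vapply(results, `[[`, character(1), "safety_category"),
      levels = c("I", "II"))),
    mating_counts = table(factor(
      vapply(results, `[[`, character(1), "mating_type"),
      levels = c("A", "B", "undetermined", "conflict")))
  )
  structure(results, class = "chemotype_results", summary = summary)
}

#' @export
as.data.frame.chemotype_results <- function(x, ...) {
  rows <- lapply(unclass(x), function(r) data.frame(
    strain = r$strain_id,
    mating_type = r$mating_type,
    ppz_allele = r$ppz_allele,
    pattern_PPZ = r$pattern_codes[["PPZ"]],
    pattern_EAS = r$pattern_codes[["EAS"]],
    pattern_IDT = r$pattern_codes[["IDT"]],
    pattern_LOL = r$pattern_codes[["LOL"]],
    producible = paste(r$producible, collapse = ","),
    chem_type = r$chem_type,
    safety_category = r$safety_category,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.chemotype_results <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("chemotype_results: %d strain(s)\n", s$n))
  cat("  types:      ", paste(sprintf("%s=%d", names(s$type_counts),
                                      s$type_counts), collapse = " "), "\n")
  cat("  categories: ", paste(sprintf("%s=%d", names(s$category_counts),
                                      s$category_counts), collapse = " "), "\n")
  cat("  mating:     ", paste(sprintf("%s=%d", names(s$mating_counts),
                                      s$mating_counts), collapse = " "), "\n")
  invisible(x)
}
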
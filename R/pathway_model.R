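# Declarative dependency models of the four alkaloid biosynthesis pathways
# (PPZ/peramine, EAS/ergot, IDT/indole-diterpene, LOL/loline) plus the
# mating-type locus.  A model is a DAG of metabolites; each production step
# is gated by an all-of set of gene markers and, optionally, a precursor
# metabolite.

.CLUSTERS <- c("PPZ", "EAS", "IDT", "LOL", "MAT")

.PPZ_DOMAINS <- c("ppzA-A1", "ppzA-T1", "ppzA-C", "ppzA-A2",
                  "ppzA-M", "ppzA-T2", "ppzA-R", "ppzA-dR")
.EAS_GENES <- c("dmaW", "easF", "easC", "easE", "easD", "easA", "easG",
                "cloA", "lpsB", "lpsA", "easH", "lpsC", "easO", "easP")
.EAS_CORE11 <- setdiff(.EAS_GENES, c("lpsC", "easO", "easP"))
.IDT_GENES <- c("idtG", "idtB", "idtM", "idtC", "idtS", "idtP", "idtQ",
                "idtF", "idtK", "idtE", "idtJ")
.IDT_CORE5 <- c("idtG", "idtB", "idtM", "idtC", "idtS")
# lolC..lolU gate the first committed intermediate (AcAP); the remaining six
# cluster genes act downstream as one block.
.LOL_ACAP_GENES <- c("lolC", "lolF", "lolD", "lolT", "lolU")
.LOL_DOWNSTREAM <- c("lolA", "lolO", "lolP", "lolE", "lolN", "lolM")
.LOL_GENES <- c(.LOL_ACAP_GENES, .LOL_DOWNSTREAM)
.MAT_GENES <- c("mtAC", "mtBA")

# Header/gene aliases accepted on input.  idtO is a known synonym slip for
# idtQ in parts of the literature; bare ppzA domain tokens are accepted as
# column headers.
.MARKER_ALIASES <- local({
  a <- c(
    "idtO" = "idtQ",
    "dR"   = "ppzA-dR",
    "R"    = "ppzA-R",
    "A1" = "ppzA-A1", "T1" = "ppzA-T1", "C" = "ppzA-C",
    "A2" = "ppzA-A2", "M"  = "ppzA-M",  "T2" = "ppzA-T2"
  )
  # U+2206 (increment) and U+0394 (greek delta) both appear in the wild
  for (delta in c("\u2206", "\u0394")) {
    a[paste0(delta, "R")] <- "ppzA-dR"
    a[paste0("ppzA-", delta, "R")] <- "ppzA-dR"
  }
  a
})

.METABOLITES <- data.frame(
  id = c("PER", "PPZ-dione",
         "CC", "D-LC", "ERV", "EN", "LAH",
         "PAS", "PAX", "TDK", "LTM-B",
         "AcAP", "NFL", "NAL"),
  name = c("peramine", "pyrrolopyrazine-1,4-diones",
           "chanoclavine I", "D-lysergic acid", "ergovaline",
           "ergonovine", "lysergic acid alpha-hydroxyacetamide",
           "paspaline", "paxilline", "terpendole K", "lolitrem B",
           "1-acetamido-pyrrolizidine", "N-formylloline", "N-acetylloline"),
  cluster = c("PPZ", "PPZ",
              "EAS", "EAS", "EAS", "EAS", "EAS",
              "IDT", "IDT", "IDT", "IDT",
              "LOL", "LOL", "LOL"),
  stringsAsFactors = FALSE
)

#' Validation error condition
#'
#' Input-validation failures throughout the package are signalled with a
#' condition of class \code{"chemotypeR_validation_error"} so callers (in
#' particular the command-line driver) can distinguish bad input from
#' internal errors.
#'
#' @param msg error message.
#' @param ... named fields attached to the condition.
#' @keywords internal
abort_validation <- function(msg, ...) {
  stop(errorCondition(msg, ...,
                      class = c("chemotypeR_validation_error", "error")))
}

#' Registry of gene and domain markers
#'
#' All PCR markers the bundled pathway models refer to: the two mating-type
#' idiomorphs (mtAC/mtBA), the eight ppzA segments (six common domains plus
#' the mutually exclusive R and dR reductase variants), 14 ergot-alkaloid
#' (EAS) genes, 11 indole-diterpene (IDT/LTM) genes and 11 loline (LOL)
#' genes.
#'
#' @return A data frame with columns \code{id} and \code{cluster}
#'   (one of PPZ, EAS, IDT, LOL, MAT).
#' @export
#' @examples
#' table(marker_registry()$cluster)
marker_registry <- function() {
  data.frame(
    id = c(.MAT_GENES, .PPZ_DOMAINS, .EAS_GENES, .IDT_GENES, .LOL_GENES),
    cluster = rep(c("MAT", "PPZ", "EAS", "IDT", "LOL"),
                  c(length(.MAT_GENES), length(.PPZ_DOMAINS),
                    length(.EAS_GENES), length(.IDT_GENES),
                    length(.LOL_GENES))),
    stringsAsFactors = FALSE
  )
}

#' Metabolite catalogue
#'
#' @return Data frame with columns \code{id} (abbreviation used throughout),
#'   \code{name} (display name) and \code{cluster}.
#' @export
metabolite_catalogue <- function() .METABOLITES

# Resolve a vector of marker names through the alias table.  Unknown names
# are returned unchanged (callers decide whether that is an error).
resolve_marker_names <- function(x, warn_alias = TRUE) {
  hit <- match(x, names(.MARKER_ALIASES))
  out <- ifelse(is.na(hit), x, .MARKER_ALIASES[hit])
  if (warn_alias && any(x == "idtO"))
    warning("marker name 'idtO' read as alias of 'idtQ' ",
            "(table header vs text naming inconsistency)", call. = FALSE)
  unname(out)
}

#' Construct a pathway production step
#'
#' @param product metabolite id produced by the step.
#' @param required_genes character vector of marker ids, all of which must be
#'   present for the step to fire (all-of semantics).
#' @param precursor metabolite id that must itself be producible, or
#'   \code{NULL} for pathway entry points.
#' @param notes free-text annotation.
#' @return An object of class \code{pathway_step}.
#' @export
pathway_step <- function(product, required_genes, precursor = NULL,
                         notes = "") {
  stopifnot(is.character(product), length(product) == 1L)
  if (!is.null(precursor))
    stopifnot(is.character(precursor), length(precursor) == 1L)
  structure(list(product = product,
                 precursor = precursor,
                 required_genes = as.character(required_genes),
                 notes = notes),
            class = "pathway_step")
}

#' Construct a pathway model
#'
#' A pathway model is an ordered collection of steps forming a DAG through
#' the \code{precursor} references.  The constructor is permissive: it stores
#' what it is given and computes a topological order when one exists; use
#' \code{\link{validate_model}} to obtain structured findings, or
#' \code{\link{load_models}} which refuses invalid files outright.
#'
#' @param name model name (conventionally PPZ, EAS, IDT or LOL).
#' @param steps list of \code{\link{pathway_step}} objects.
#' @param toxic_products metabolite ids toxic to livestock.
#' @param terminal_products metabolite ids considered pathway end products;
#'   defaults to products with no successor step.
#' @return An object of class \code{pathway_model}.
#' @export
pathway_model <- function(name, steps, toxic_products = character(),
                          terminal_products = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.list(steps))
  products <- vapply(steps, function(s) s$product, character(1))
  precursors <- vapply(steps, function(s)
    if (is.null(s$precursor)) NA_character_ else s$precursor, character(1))
  if (is.null(terminal_products))
    terminal_products <- setdiff(products, stats::na.omit(precursors))
  m <- structure(list(name = name,
                      steps = steps,
                      toxic_products = as.character(toxic_products),
                      terminal_products = as.character(terminal_products)),
                 class = "pathway_model")
  m$topo_order <- topological_order(m)
  m
}

# Kahn topological sort over the precursor graph; NULL when cyclic or when a
# precursor reference dangles.
topological_order <- function(model) {
  products <- vapply(model$steps, `[[`, character(1), "product")
  prec <- lapply(model$steps, `[[`, "precursor")
  indeg <- vapply(prec, function(p) as.integer(!is.null(p)), integer(1))
  if (any(vapply(prec, function(p)
    !is.null(p) && !(p %in% products), logical(1)))) return(NULL)
  if (anyDuplicated(products)) return(NULL)
  names(indeg) <- products
  order <- character(0)
  ready <- products[indeg == 0L]
  while (length(ready)) {
    x <- ready[1L]; ready <- ready[-1L]
    order <- c(order, x)
    kids <- products[vapply(prec, function(p)
      !is.null(p) && p == x, logical(1))]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(order) != length(products)) return(NULL)
  order
}

#' Validate a pathway model
#'
#' Checks the structural invariants: gates are non-vacuous (a step must
#' require at least one gene or a precursor), products are unique, precursor
#' references resolve, the precursor graph is acyclic, required genes are
#' registered markers, and the toxic/terminal sets only name declared
#' products.
#'
#' @param model a \code{\link{pathway_model}}.
#' @return A data frame of findings with columns \code{severity}
#'   (\code{"error"} or \code{"warning"}), \code{step} and \code{message};
#'   zero rows when every invariant holds.
#' @export
validate_model <- function(model) {
  findings <- list()
  add <- function(severity, step, message)
    findings[[length(findings) + 1L]] <<-
      data.frame(severity = severity, step = step, message = message,
                 stringsAsFactors = FALSE)
  products <- vapply(model$steps, `[[`, character(1), "product")
  dup <- unique(products[duplicated(products)])
  for (d in dup) add("error", d, "duplicate product")
  registered <- marker_registry()$id
  for (s in model$steps) {
    if (length(s$required_genes) == 0L && is.null(s$precursor))
      add("error", s$product, "vacuous step: no required genes and no precursor")
    if (!is.null(s$precursor) && !(s$precursor %in% products))
      add("error", s$product,
          sprintf("precursor '%s' is not produced by any step", s$precursor))
    bad <- setdiff(s$required_genes, registered)
    if (length(bad))
      add("warning", s$product,
          sprintf("unregistered marker(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(model$topo_order) && !length(dup) &&
      !any(vapply(model$steps, function(s)
        !is.null(s$precursor) && !(s$precursor %in% products), logical(1))))
    add("error", NA_character_, "precursor graph contains a cycle")
  for (what in c("toxic_products", "terminal_products")) {
    bad <- setdiff(model[[what]], products)
    if (length(bad))
      add("error", NA_character_,
          sprintf("%s not among declared products: %s",
                  what, paste(bad, collapse = ", ")))
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(severity = character(), step = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Built-in default pathway models
#'
#' The bundled gating of the four pathways:
#' \describe{
#'   \item{PPZ}{peramine (PER) requires the seven ppzA segments including the
#'     reductase (R) domain; with the dR variant in place of R the release
#'     step is missing and pyrrolopyrazine-1,4-diones (PPZ-dione) are made
#'     instead.  Neither product is toxic to livestock.}
#'   \item{EAS}{chanoclavine I (CC) from the four early genes; D-lysergic
#'     acid (D-LC) then ergovaline (ERV) downstream; ergonovine (EN, via
#'     lpsC) and lysergic acid alpha-hydroxyacetamide (LAH, via easO/easP)
#'     gated at the end of the pathway.  All products toxic.}
#'   \item{IDT}{paspaline (PAS) from the five-gene core; paxilline (PAX, via
#'     idtP/idtQ), terpendole K (TDK, via idtF/idtK) and lolitrem B (LTM-B,
#'     via idtE/idtJ) downstream.  All products toxic.}
#'   \item{LOL}{the first committed intermediate AcAP requires lolC, lolF,
#'     lolD, lolT and lolU simultaneously; N-formylloline and N-acetylloline
#'     each additionally require the remaining six cluster genes as one
#'     block.  Lolines are insect-active but livestock-safe: not toxic.}
#' }
#'
#' @return Named list of four \code{\link{pathway_model}} objects in
#'   pathway order PPZ, EAS, IDT, LOL.
#' @export
#' @examples
#' names(default_models())
default_models <- function() {
  ppz_common <- c("ppzA-A1", "ppzA-T1", "ppzA-C", "ppzA-A2",
                  "ppzA-M", "ppzA-T2")
  ppz <- pathway_model("PPZ", list(
    pathway_step("PER", c(ppz_common, "ppzA-R"),
                 notes = "full-length ppzA (allele ppzA-1)"),
    pathway_step("PPZ-dione", c(ppz_common, "ppzA-dR"),
                 notes = "reductase-less ppzA (allele ppzA-2)")
  ), toxic_products = character())
  eas <- pathway_model("EAS", list(
    pathway_step("CC", c("dmaW", "easF", "easC", "easE")),
    pathway_step("D-LC", c("easD", "easA", "easG", "cloA"), precursor = "CC"),
    pathway_step("ERV", c("lpsA", "lpsB", "easH"), precursor = "D-LC"),
    pathway_step("EN", "lpsC", precursor = "D-LC"),
    pathway_step("LAH", c("easO", "easP"), precursor = "EN")
  ), toxic_products = c("CC", "D-LC", "ERV", "EN", "LAH"))
  idt <- pathway_model("IDT", list(
    pathway_step("PAS", .IDT_CORE5),
    pathway_step("PAX", c("idtP", "idtQ"), precursor = "PAS"),
    pathway_step("TDK", c("idtF", "idtK"), precursor = "PAX"),
    pathway_step("LTM-B", c("idtE", "idtJ"), precursor = "TDK")
  ), toxic_products = c("PAS", "PAX", "TDK", "LTM-B"))
  lol <- pathway_model("LOL", list(
    pathway_step("AcAP", .LOL_ACAP_GENES,
                 notes = "all five genes required simultaneously"),
    pathway_step("NFL", .LOL_DOWNSTREAM, precursor = "AcAP"),
    pathway_step("NAL", .LOL_DOWNSTREAM, precursor = "AcAP")
  ), toxic_products = character())
  list(PPZ = ppz, EAS = eas, IDT = idt, LOL = lol)
}

# Convert a parsed list (from YAML/JSON) into a pathway_model, checking the
# schema shape.  `file` is used only for error messages.
model_from_list <- function(x, file = "<list>") {
  need <- c("name", "steps")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort_validation(sprintf("%s: missing top-level field(s): %s",
                             file, paste(miss, collapse = ", ")))
  if (!is.list(x$steps) || length(x$steps) == 0L)
    abort_validation(sprintf("%s: 'steps' must be a non-empty list", file))
  steps <- lapply(seq_along(x$steps), function(i) {
    s <- x$steps[[i]]
    if (is.null(s$product) || !nzchar(s$product))
      abort_validation(sprintf("%s: step %d: missing 'product'", file, i))
    prec <- s$precursor
    if (!is.null(prec) && (is.na(prec) || identical(prec, "")))
      prec <- NULL
    genes <- resolve_marker_names(as.character(unlist(s$required_genes)))
    pathway_step(as.character(s$product), genes, precursor = prec,
                 notes = if (is.null(s$notes)) "" else as.character(s$notes))
  })
  m <- pathway_model(as.character(x$name), steps,
                     toxic_products = as.character(unlist(x$toxic_products)),
                     terminal_products =
                       if (is.null(x$terminal_products)) NULL
                       else as.character(unlist(x$terminal_products)))
  f <- validate_model(m)
  errs <- f[f$severity == "error", , drop = FALSE]
  if (nrow(errs))
    abort_validation(sprintf(
      "%s: invalid model '%s': %s", file, m$name,
      paste(sprintf("[step %s] %s", ifelse(is.na(errs$step), "-", errs$step),
                    errs$message), collapse = "; ")))
  m
}

#' Load pathway models
#'
#' With no arguments returns the built-in defaults
#' (\code{\link{default_models}}).  Given file paths, reads each YAML or
#' JSON model file, resolves marker-name aliases, and refuses files that
#' violate the model schema or whose precursor graph is cyclic.
#'
#' @param files character vector of model file paths, or \code{NULL} for the
#'   built-in registry.
#' @return Named list of \code{\link{pathway_model}} objects.
#' @export
load_models <- function(files = NULL) {
  if (is.null(files) || identical(files, "builtin"))
    return(default_models())
  models <- lapply(files, function(f) {
    if (!file.exists(f))
      abort_validation(sprintf("model file not found: %s", f))
    x <- if (grepl("\\.json$", f, ignore.case = TRUE))
      jsonlite::read_json(f, simplifyVector = FALSE)
    else yaml::read_yaml(f)
    model_from_list(x, file = f)
  })
  names(models) <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(names(models)))
    abort_validation("duplicate model names across files")
  models
}

# Plain-list form used for serialization; inverse of model_from_list for
# valid models.
model_to_list <- function(model) {
  list(
    name = model$name,
    steps = lapply(model$steps, function(s) {
      list(product = s$product,
           precursor = if (is.null(s$precursor)) NULL else s$precursor,
           required_genes = as.list(s$required_genes))
    }),
    terminal_products = as.list(model$terminal_products),
    toxic_products = as.list(model$toxic_products)
  )
}

#' Write a pathway model to YAML or JSON
#'
#' @param model a \code{\link{pathway_model}}.
#' @param path output file; format chosen by extension (\code{.json} writes
#'   JSON, anything else YAML).
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  x <- model_to_list(model)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("Pathway model '%s': %d steps\n", x$name, length(x$steps)))
  for (s in x$steps)
    cat(sprintf("  %-9s <- genes {%s}%s\n", s$product,
                paste(s$required_genes, collapse = ", "),
                if (is.null(s$precursor)) ""
                else sprintf(" + precursor %s", s$precursor)))
  cat(sprintf("  terminal: %s\n",
              paste(x$terminal_products, collapse = ", ")))
  cat(sprintf("  toxic:    %s\n",
              if (length(x$toxic_products))
                paste(x$toxic_products, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Markers and products referenced by a model
#'
#' \code{model_markers} returns every gene marker a model's gates
#' reference; \code{model_products} returns the metabolite ids in step
#' (pathway) order.
#'
#' @param model a \code{\link{pathway_model}}.
#' @return Character vector.
#' @export
model_markers <- function(model)
  unique(unlist(lapply(model$steps, `[[`, "required_genes")))

#' @rdname model_markers
#' @export
model_products <- function(model)
  vapply(model$steps, `[[`, character(1), "product")
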
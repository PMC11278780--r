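# Shared test helpers: quick construction of call vectors and random
# tri-state profiles.

all_markers <- marker_registry()$id

# Named tri-state vector over all registered markers: everything `default`,
# with `present`/`absent`/`unknown` overrides.
make_calls <- function(present = character(), absent = character(),
                       unknown = character(), default = "absent") {
  calls <- stats::setNames(rep(default, length(all_markers)), all_markers)
  calls[present] <- "present"
  calls[absent] <- "absent"
  calls[unknown] <- "unknown"
  calls
}

# Random tri-state profile over the given markers.
random_calls <- function(markers = all_markers,
                         p = c(present = 0.5, absent = 0.4, unknown = 0.1)) {
  stats::setNames(sample(names(p), length(markers), replace = TRUE,
                         prob = p), markers)
}

# Wrap a single call vector as a one-row gene_profiles object.
as_profiles <- function(calls, strain = "S1") {
  m <- matrix(calls, nrow = 1, dimnames = list(strain, names(calls)))
  structure(m, class = "gene_profiles",
            host = stats::setNames(character(0), character(0)),
            location = stats::setNames(character(0), character(0)))
}

fixture_profiles <- function()
  suppressMessages(read_profiles(chemotype_example("elymus_profiles.tsv")))

fixture_survey <- function()
  read_survey(chemotype_example("elymus_survey.tsv"))
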
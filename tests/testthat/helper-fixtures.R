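# Shared fixtures, all built in code.

# ICD10-style chain with a sibling branch, as in the impacted-cerumen
# worked example: H61.23 -> H61.2 -> H61, plus H60 with one child.
icd_chain_ontology <- function() {
  build_ontology(data.frame(
    child = c("H61.23", "H61.2", "H60.1"),
    parent = c("H61.2", "H61", "H60"),
    primary = TRUE,
    domain = "condition",
    stringsAsFactors = FALSE
  ))
}

# depth-1 ontology: every code hangs directly off the virtual domain root
flat_ontology <- function(n = 6) {
  build_ontology(data.frame(
    child = sprintf("F%02d", seq_len(n)),
    parent = "",
    primary = TRUE,
    domain = "condition",
    stringsAsFactors = FALSE
  ))
}

# random primary-parent forest for property tests
random_forest_ontology <- function(n_nodes = 30, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  parent <- character(n_nodes)
  parent[1] <- NA
  for (i in 2:n_nodes) parent[i] <- nodes[sample.int(i - 1L, 1)]
  build_ontology(data.frame(
    child = nodes[-1], parent = parent[-1], primary = TRUE,
    domain = "condition", stringsAsFactors = FALSE
  ))
}

# small population memoized across test files
.pop_cache <- new.env(parent = emptyenv())
small_population <- function() {
  if (is.null(.pop_cache$pop)) {
    .pop_cache$pop <- generate_population(generator_config(
      n_patients = 250, year_range = c(2009, 2012),
      ontology = make_synthetic_ontology(2, 3), seed = 42
    ))
  }
  .pop_cache$pop
}

# single-patient demographics row
demo_row_fixture <- function(birth_day = -43L * 365L, sex = "F") {
  list(patient_id = "P1", birth_day = birth_day, sex = sex,
       race = "white", ethnicity = "non-hispanic")
}
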
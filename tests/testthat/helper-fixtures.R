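# Shared fixtures built in code.

# plain accessors so tests do not poke at package internals
schema_fact_names_of <- function(s) vapply(s$fact_types, `[[`, "", "name")
entity_names_of <- function(s) vapply(s$entity_types, `[[`, "", "name")

toy_schema <- function() {
  fact_schema(
    fact_types = list(
      fact_type("Lesion", "LesionAnchor", c("Size", "Negation")),
      fact_type("Birads", "BiradsAnchor", c("Value"))),
    entity_types = list(
      entity_type("LesionAnchor", "anchor"),
      entity_type("BiradsAnchor", "anchor"),
      entity_type("Size", "modifier"),
      entity_type("Negation", "modifier"),
      entity_type("Value", "modifier")),
    version = "toy", min_class_frequency = 20L)
}

# a full-report schema of 24 fact types and 66 modifier types, with an
# annotation-count map splitting it into 14 retained facts / 26 retained
# modifiers, 4 + 26 unobserved and 6 + 14 rare elements
padded_schema_with_counts <- function() {
  fact_names <- sprintf("F%02d", 1:24)
  anchor_names <- sprintf("F%02d_anchor", 1:24)
  mod_names <- sprintf("M%02d", 1:66)
  # frequent modifiers M01-M26 attach round-robin to retained facts F01-F14;
  # rare (M27-M40) and unobserved (M41-M66) modifiers round-robin over all
  slots <- setNames(lapply(1:24, function(i) character()), fact_names)
  for (m in 1:26) {
    f <- fact_names[(m - 1L) %% 14L + 1L]
    slots[[f]] <- c(slots[[f]], mod_names[m])
  }
  for (m in 27:66) {
    f <- fact_names[(m - 1L) %% 24L + 1L]
    slots[[f]] <- c(slots[[f]], mod_names[m])
  }
  ets <- c(lapply(anchor_names, function(a) entity_type(a, "anchor")),
           lapply(mod_names, function(m) entity_type(m, "modifier")))
  fts <- lapply(1:24, function(i) {
    fact_type(fact_names[i], anchor_names[i], slots[[fact_names[i]]])
  })
  schema <- fact_schema(fts, ets, version = "padded", min_class_frequency = 20L)
  counts <- c(setNames(rep(50, 14), fact_names[1:14]),      # retained facts
              setNames(rep(5, 6), fact_names[15:20]),       # rare facts
              setNames(rep(0, 4), fact_names[21:24]),       # unobserved facts
              setNames(rep(40, 26), mod_names[1:26]),       # retained modifiers
              setNames(rep(7, 14), mod_names[27:40]),       # rare modifiers
              setNames(rep(0, 26), mod_names[41:66]))       # unobserved modifiers
  list(schema = schema, counts = counts)
}

# small annotated document built by hand over a known findings text
tiny_annotated_doc <- function() {
  findings <- "Keine Läsion beidseits. BI-RADS 1 links."
  doc <- report_document("doc-1", "mammography",
                         list(findings = findings), birads = 1L)
  f1 <- fact_instance("Lesion", 0L, 22L, list(
    entity_span("Negation", 0L, 5L, "Keine"),
    entity_span("LesionAnchor", 6L, 12L, "Läsion")))
  f2 <- fact_instance("Birads", 24L, 39L, list(
    entity_span("BiradsAnchor", 24L, 31L, "BI-RADS"),
    entity_span("Value", 32L, 33L, "1")))
  annotated_document(doc, list(f1, f2))
}
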
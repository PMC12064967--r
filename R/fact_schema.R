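# Frame-semantics information model: a fact is a continuous text span typed by
# a FactType, carrying exactly one anchor entity (the keyword identifying the
# fact) and any number of modifier entities (size, location, negation, ...).

#' Declare an entity type
#'
#' Entity types are the atomic annotation labels of the information model.
#' Every fact type owns exactly one entity type with role `"anchor"`; all
#' other entity types attached to a fact are `"modifier"`s.
#'
#' @param name Identifier string, unique within a schema.
#' @param role Either `"anchor"` or `"modifier"`.
#' @param definition Free-text description shown to annotators.
#' @return An object of class `ff_entity_type`.
#' @export
entity_type <- function(name, role = c("modifier", "anchor"), definition = "") {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, role = role, definition = definition),
            class = "ff_entity_type")
}

#' Declare a fact type
#'
#' @param name Identifier string.
#' @param anchor Name of the anchor entity type.
#' @param modifier_slots Character vector of modifier entity-type names this
#'   fact admits. Must not repeat and must not contain the anchor.
#' @param definition Free-text description.
#' @return An object of class `ff_fact_type`.
#' @export
fact_type <- function(name, anchor, modifier_slots = character(), definition = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(anchor), length(anchor) == 1L,
            is.character(modifier_slots))
  structure(list(name = name, anchor = anchor,
                 modifier_slots = modifier_slots, definition = definition),
            class = "ff_fact_type")
}

#' Assemble a fact schema
#'
#' A schema bundles fact types with the entity types they reference, plus the
#' minimum class frequency used by [apply_frequency_filter()]. Construction is
#' permissive: structural problems are reported by [validate_schema()], not
#' rejected here, so that invalid schemas can be loaded and diagnosed.
#'
#' @param fact_types List of [fact_type()] objects.
#' @param entity_types List of [entity_type()] objects.
#' @param version Free-form schema version string.
#' @param min_class_frequency Annotation count below which a class is dropped
#'   during frequency filtering (default 20).
#' @return An object of class `ff_schema`.
#' @export
fact_schema <- function(fact_types, entity_types, version = "1.0",
                        min_class_frequency = 20L) {
  stopifnot(is.list(fact_types), is.list(entity_types),
            is.numeric(min_class_frequency), min_class_frequency >= 0)
  structure(list(fact_types = unname(fact_types),
                 entity_types = unname(entity_types),
                 version = as.character(version),
                 min_class_frequency = as.integer(min_class_frequency)),
            class = "ff_schema")
}

#' @export
print.ff_schema <- function(x, ...) {
  roles <- vapply(x$entity_types, `[[`, "", "role")
  cat(sprintf("<fact schema '%s': %d fact types, %d entity types (%d anchors, %d modifiers), min class frequency %d>\n",
              x$version, length(x$fact_types), length(x$entity_types),
              sum(roles == "anchor"), sum(roles == "modifier"),
              x$min_class_frequency))
  invisible(x)
}

schema_entity_names <- function(schema) {
  vapply(schema$entity_types, `[[`, "", "name")
}

schema_fact_names <- function(schema) {
  vapply(schema$fact_types, `[[`, "", "name")
}

schema_entity <- function(schema, name) {
  idx <- match(name, schema_entity_names(schema))
  if (is.na(idx)) NULL else schema$entity_types[[idx]]
}

schema_fact <- function(schema, name) {
  idx <- match(name, schema_fact_names(schema))
  if (is.na(idx)) NULL else schema$fact_types[[idx]]
}

issue_df <- function(code = character(), name = character(), message = character()) {
  structure(data.frame(code = code, name = name, message = message,
                       stringsAsFactors = FALSE),
            class = c("ff_validation_report", "data.frame"))
}

#' Validate a fact schema
#'
#' Checks the structural invariants of the information model: unique names,
#' every referenced entity declared, exactly one anchor per fact type with
#' role `"anchor"`, no duplicate or anchor-containing modifier slots, and an
#' entity inventory that is exactly the set of referenced anchors and
#' modifiers.
#'
#' @param schema An `ff_schema`.
#' @return A data frame of issues with columns `code`, `name`, `message`
#'   (class `ff_validation_report`); zero rows iff the schema is valid.
#'   Issue codes: `DUPLICATE_NAME`, `UNDECLARED_ENTITY`, `MULTIPLE_ANCHORS`,
#'   `NOT_AN_ANCHOR`, `ANCHOR_IN_SLOTS`, `DUPLICATE_SLOT`, `UNUSED_ENTITY`.
#' @export
validate_schema <- function(schema) {
  if (!inherits(schema, "ff_schema")) {
    stop("not a fact schema; parse input with read_fact_schema() first", call. = FALSE)
  }
  codes <- character(); names_ <- character(); msgs <- character()
  add <- function(code, name, msg) {
    codes <<- c(codes, code); names_ <<- c(names_, name); msgs <<- c(msgs, msg)
  }

  enames <- schema_entity_names(schema)
  fnames <- schema_fact_names(schema)
  for (nm in unique(enames[duplicated(enames)])) {
    add("DUPLICATE_NAME", nm, sprintf("entity type '%s' declared more than once", nm))
  }
  for (nm in unique(fnames[duplicated(fnames)])) {
    add("DUPLICATE_NAME", nm, sprintf("fact type '%s' declared more than once", nm))
  }

  roles <- vapply(schema$entity_types, `[[`, "", "role")
  for (ft in schema$fact_types) {
    refs <- c(ft$anchor, ft$modifier_slots)
    for (r in refs[!(refs %in% enames)]) {
      add("UNDECLARED_ENTITY", r,
          sprintf("fact type '%s' references undeclared entity '%s'", ft$name, r))
    }
    anchor_roles <- roles[match(ft$anchor, enames)]
    if (!is.na(anchor_roles) && anchor_roles != "anchor") {
      add("NOT_AN_ANCHOR", ft$anchor,
          sprintf("fact type '%s' uses '%s' as anchor but its role is '%s'",
                  ft$name, ft$anchor, anchor_roles))
    }
    slot_roles <- roles[match(ft$modifier_slots, enames)]
    anchors_in_slots <- ft$modifier_slots[!is.na(slot_roles) & slot_roles == "anchor"]
    if (ft$anchor %in% ft$modifier_slots || length(anchors_in_slots) > 0L) {
      offending <- unique(c(intersect(ft$anchor, ft$modifier_slots), anchors_in_slots))
      for (nm in offending) {
        code <- if (nm == ft$anchor) "ANCHOR_IN_SLOTS" else "MULTIPLE_ANCHORS"
        add(code, nm,
            sprintf("fact type '%s' lists anchor-role entity '%s' among modifier slots",
                    ft$name, nm))
      }
    }
    for (nm in unique(ft$modifier_slots[duplicated(ft$modifier_slots)])) {
      add("DUPLICATE_SLOT", nm,
          sprintf("fact type '%s' repeats modifier slot '%s'", ft$name, nm))
    }
  }

  used <- unique(unlist(lapply(schema$fact_types,
                               function(ft) c(ft$anchor, ft$modifier_slots))))
  for (nm in setdiff(enames, used)) {
    add("UNUSED_ENTITY", nm,
        sprintf("entity type '%s' is not referenced by any fact type", nm))
  }

  issue_df(codes, names_, msgs)
}

#' Frequency-filter a schema against observed annotation counts
#'
#' Drops fact types annotated fewer than `min_class_frequency` times together
#' with their anchors (unless another retained fact shares the anchor), then
#' drops under-threshold modifier slots from the remaining fact types. Counts
#' for modifiers shared across fact types are global per entity name. Elements
#' with a count of zero (or absent from `counts`) are reported as unobserved;
#' elements with a positive count below the threshold as rare.
#'
#' @param schema An `ff_schema`.
#' @param counts Named numeric vector (or single-level list) mapping fact-type
#'   and entity-type names to annotation counts; names absent from `counts`
#'   count as 0.
#' @return A list with elements `schema` (the retained subset, an `ff_schema`)
#'   and `report` (class `ff_filter_report`): character vectors
#'   `facts_unobserved`, `facts_rare`, `modifiers_unobserved`,
#'   `modifiers_rare`, plus `retained_facts` and `retained_entities`.
#' @export
apply_frequency_filter <- function(schema, counts) {
  counts <- unlist(counts)
  if (length(counts) && any(counts < 0)) {
    stop("negative annotation counts are invalid", call. = FALSE)
  }
  cnt <- function(nm) {
    v <- counts[nm]
    ifelse(is.na(v), 0, v)
  }
  min_n <- schema$min_class_frequency

  fnames <- schema_fact_names(schema)
  fcounts <- cnt(fnames)
  keep_fact <- fcounts >= min_n
  facts_unobserved <- fnames[fcounts == 0]
  facts_rare <- fnames[fcounts > 0 & !keep_fact]

  kept_facts <- schema$fact_types[keep_fact]

  # modifiers judged on globally aggregated counts, over all slots in schema
  all_mods <- unique(unlist(lapply(schema$fact_types, `[[`, "modifier_slots")))
  mcounts <- cnt(all_mods)
  mods_unobserved <- all_mods[mcounts == 0]
  mods_rare <- all_mods[mcounts > 0 & mcounts < min_n]
  drop_mods <- c(mods_unobserved, mods_rare)

  kept_facts <- lapply(kept_facts, function(ft) {
    ft$modifier_slots <- setdiff(ft$modifier_slots, drop_mods)
    ft
  })

  used <- unique(unlist(lapply(kept_facts, function(ft) c(ft$anchor, ft$modifier_slots))))
  if (is.null(used)) used <- character()
  kept_entities <- Filter(function(et) et$name %in% used, schema$entity_types)

  out <- fact_schema(kept_facts, kept_entities, version = schema$version,
                     min_class_frequency = min_n)
  report <- structure(list(
    facts_unobserved = facts_unobserved,
    facts_rare = facts_rare,
    modifiers_unobserved = mods_unobserved,
    modifiers_rare = mods_rare,
    retained_facts = schema_fact_names(out),
    retained_entities = schema_entity_names(out)
  ), class = "ff_filter_report")
  list(schema = out, report = report)
}

#' @export
print.ff_filter_report <- function(x, ...) {
  cat(sprintf("<frequency filter: retained %d facts / %d entities; removed %d unobserved + %d rare facts, %d unobserved + %d rare modifiers>\n",
              length(x$retained_facts), length(x$retained_entities),
              length(x$facts_unobserved), length(x$facts_rare),
              length(x$modifiers_unobserved), length(x$modifiers_rare)))
  invisible(x)
}

#' IOB label inventory of a schema
#'
#' @param schema An `ff_schema`.
#' @return Character vector `c("O", "B-e1", "I-e1", ...)` over entity types in
#'   declaration order; length `2 * n_entity_types + 1`.
#' @export
label_inventory <- function(schema) {
  enames <- schema_entity_names(schema)
  if (length(enames) == 0L) return("O")
  c("O", as.vector(rbind(paste0("B-", enames), paste0("I-", enames))))
}

#' Read a fact schema from JSON
#'
#' Expects a UTF-8 JSON document with top-level keys `version`,
#' `min_class_frequency`, `entity_types` (objects with `name`, `role`,
#' `definition`) and `fact_types` (objects with `name`, `anchor`,
#' `modifier_slots`, `definition`).
#'
#' @param path Path to the JSON file.
#' @return An `ff_schema`. Signals a format error (class `ff_format_error`)
#'   for unreadable or non-JSON input; structural problems are left to
#'   [validate_schema()].
#' @export
read_fact_schema <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    stop(structure(class = c("ff_format_error", "error", "condition"),
                                   list(message = sprintf("cannot parse schema JSON '%s': %s",
                                                          path, conditionMessage(e)),
                                        call = NULL)))
                  })
  required <- c("version", "min_class_frequency", "entity_types", "fact_types")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(structure(class = c("ff_format_error", "error", "condition"),
                   list(message = sprintf("schema JSON misses top-level keys: %s",
                                          paste(missing, collapse = ", ")),
                        call = NULL)))
  }
  ets <- lapply(raw$entity_types, function(e) {
    entity_type(e$name, e$role, definition = e$definition %||% "")
  })
  fts <- lapply(raw$fact_types, function(f) {
    fact_type(f$name, f$anchor,
              modifier_slots = as.character(unlist(f$modifier_slots %||% list())),
              definition = f$definition %||% "")
  })
  fact_schema(fts, ets, version = raw$version,
              min_class_frequency = raw$min_class_frequency)
}

#' Write a fact schema to JSON
#'
#' @param schema An `ff_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fact_schema <- function(schema, path) {
  out <- list(
    version = schema$version,
    min_class_frequency = schema$min_class_frequency,
    entity_types = lapply(schema$entity_types, function(e) {
      list(name = e$name, role = e$role, definition = e$definition)
    }),
    fact_types = lapply(schema$fact_types, function(f) {
      list(name = f$name, anchor = f$anchor,
           modifier_slots = as.list(f$modifier_slots), definition = f$definition)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
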
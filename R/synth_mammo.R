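# Synthetic mammography-style reports with exact gold annotations. Findings
# sections are assembled from German-styled clause templates conditioned on
# the BI-RADS category; every rendered clause yields the fact span and all
# entity spans with exact character offsets, so generated corpora close the
# loop with the validator, the converters and the rule-based pipeline
# backends. Linguistic realism is not a goal; offset and schema fidelity are.

lit <- function(x) list(lit = x)
slt <- function(type, options) list(slot = type, options = options)

size_options <- function() {
  as.vector(outer(c(5L, 8L, 11L, 14L, 17L, 19L, 22L, 25L),
                  c(4L, 7L, 9L, 12L, 15L, 18L),
                  function(a, b) paste0(a, " x ", b, " mm")))
}

quadrant_options <- c("oberen äußeren", "oberen inneren",
                      "unteren äußeren", "unteren inneren")

#' The demonstration mammography fact schema
#'
#' A 14-fact schema mirroring the content of a typical mammography findings
#' section: lesions (with shape, size, quadrant, o'clock position, side,
#' negation), calcifications, nipple distance, ACR density, lymph nodes,
#' BI-RADS statements, follow-up recommendations, skin, asymmetry, foreign
#' material, the mamilla region, prior examinations, malignancy statements
#' and architectural distortions. 14 anchor and 16 modifier entity types.
#' Clinical completeness is not claimed.
#'
#' @return An `ff_schema`.
#' @export
demo_schema <- function() {
  anchors <- c(Lesion = "LesionAnchor",
               Calcification = "CalcificationAnchor",
               NippleDistance = "NippleDistanceAnchor",
               Density = "DensityAnchor",
               LymphNodes = "LymphNodeAnchor",
               BiradsStatement = "BiradsAnchor",
               Recommendation = "RecommendationAnchor",
               SkinFinding = "SkinAnchor",
               Asymmetry = "AsymmetryAnchor",
               ForeignMaterial = "ForeignMaterialAnchor",
               MamillaRegion = "MamillaAnchor",
               PriorExams = "PriorExamAnchor",
               AdditionalResult = "MalignancyAnchor",
               ArchitecturalDistortion = "DistortionAnchor")
  modifiers <- c("Negation", "Side", "Quadrant", "Shape", "Size",
                 "ClockPosition", "CalcType", "Measure", "DensityClass",
                 "Suspicion", "BiradsValue", "Interval", "Procedure",
                 "Finding", "MaterialType", "PriorDate")
  slots <- list(
    Lesion = c("Negation", "Side", "Quadrant", "Shape", "Size", "ClockPosition"),
    Calcification = c("Negation", "Side", "Quadrant", "CalcType"),
    NippleDistance = "Measure",
    Density = c("DensityClass", "Side"),
    LymphNodes = c("Negation", "Side", "Suspicion"),
    BiradsStatement = c("BiradsValue", "Side"),
    Recommendation = c("Interval", "Procedure"),
    SkinFinding = c("Finding", "Side"),
    Asymmetry = c("Negation", "Side"),
    ForeignMaterial = c("Negation", "Side", "MaterialType"),
    MamillaRegion = c("Finding", "Side"),
    PriorExams = c("Negation", "PriorDate"),
    AdditionalResult = "Negation",
    ArchitecturalDistortion = c("Negation", "Quadrant", "Side"))
  ets <- c(lapply(unname(anchors), function(a) entity_type(a, "anchor")),
           lapply(modifiers, function(m) entity_type(m, "modifier")))
  fts <- lapply(names(anchors), function(f) {
    fact_type(f, anchors[[f]], modifier_slots = slots[[f]])
  })
  fact_schema(fts, ets, version = "demo-1")
}

#' The clause bank behind the synthetic generator
#'
#' Each clause template belongs to one fact type and one polarity and lists
#' the BI-RADS categories it suits. A template is a sequence of literal
#' segments and entity slots with finite filler options; rendering any filler
#' combination yields the fact span and exact gold entity spans.
#'
#' @return List of templates (class `ff_clause_bank`).
#' @export
demo_clause_bank <- function() {
  tpl <- function(fact_type, cats, polarity, ...) {
    list(fact_type = fact_type, cats = cats, polarity = polarity,
         parts = list(...))
  }
  bank <- list(
    tpl("PriorExams", 0:6, "pos",
        slt("PriorExamAnchor", "Voraufnahmen"), lit(" von "),
        slt("PriorDate", c("2015", "2017", "2019", "2021")),
        lit(" zum Vergleich vorliegend")),
    tpl("PriorExams", 0:6, "neg",
        slt("Negation", "Keine"), lit(" "),
        slt("PriorExamAnchor", "Voraufnahmen"),
        lit(" zum Vergleich vorliegend")),
    tpl("SkinFinding", 0:6, "pos",
        slt("SkinAnchor", c("Haut und Subkutis", "Kutis und Subkutis")),
        lit(" "), slt("Finding", c("unauffällig", "verdickt")),
        lit(" "), slt("Side", c("beidseits", "links", "rechts"))),
    tpl("MamillaRegion", 0:6, "pos",
        slt("MamillaAnchor", c("Mamillenregion", "Mamille")), lit(" "),
        slt("Finding", c("unauffällig", "eingezogen")), lit(" "),
        slt("Side", c("beidseits", "links", "rechts"))),
    tpl("Lesion", c(0L, 2:6), "pos",
        lit("In der "), slt("Side", c("linken", "rechten")),
        lit(" Brust zeigt sich eine "),
        slt("Shape", c("rundliche", "ovale", "irreguläre", "lobulierte")),
        lit(" "), slt("LesionAnchor", c("Läsion", "Verdichtung", "Raumforderung")),
        lit(" von "), slt("Size", size_options()),
        lit(" im "), slt("Quadrant", quadrant_options),
        lit(" Quadranten bei "), slt("ClockPosition", paste(1:12, "Uhr"))),
    tpl("Lesion", 1:2, "neg",
        slt("Negation", c("Keine", "Keinerlei")), lit(" "),
        slt("LesionAnchor", c("Läsion", "Herdbefunde")), lit(" "),
        slt("Side", c("beidseits", "links", "rechts"))),
    tpl("NippleDistance", c(0L, 2:6), "pos",
        lit("Der "), slt("NippleDistanceAnchor", "Mamillenabstand"),
        lit(" beträgt "), slt("Measure", paste(seq(10L, 90L, 5L), "mm"))),
    tpl("Calcification", 2:6, "pos",
        slt("CalcType", c("Gruppierte", "Vereinzelte", "Polymorphe")),
        lit(" "), slt("CalcificationAnchor", c("Verkalkungen", "Mikroverkalkungen")),
        lit(" im "), slt("Quadrant", quadrant_options),
        lit(" Quadranten "), slt("Side", c("links", "rechts"))),
    tpl("Calcification", 0:3, "neg",
        slt("Negation", "Keine"), lit(" "),
        slt("CalcificationAnchor", c("Mikro- oder Makroverkalkungen", "Verkalkungen")),
        lit(" "), slt("Side", c("beidseits", "links", "rechts"))),
    tpl("Asymmetry", c(0L, 4L, 5L), "pos",
        slt("AsymmetryAnchor", c("Asymmetrie", "Parenchymasymmetrie")),
        lit(" der Dichte "), slt("Side", c("links", "rechts"))),
    tpl("Asymmetry", 1:3, "neg",
        slt("Negation", "Keine"), lit(" fokale "),
        slt("AsymmetryAnchor", "Asymmetrie"), lit(" "),
        slt("Side", "beidseits")),
    tpl("ArchitecturalDistortion", 4:5, "pos",
        slt("DistortionAnchor", "Architekturstörung"), lit(" im "),
        slt("Quadrant", quadrant_options), lit(" Quadranten "),
        slt("Side", c("links", "rechts"))),
    tpl("ArchitecturalDistortion", 1:3, "neg",
        slt("Negation", "Keine"), lit(" "),
        slt("DistortionAnchor", "Architekturstörung"),
        lit(" abgrenzbar")),
    tpl("ForeignMaterial", c(2L, 6L), "pos",
        slt("MaterialType", c("Clipmarkierung", "Silikonimplantat")),
        lit(" als "), slt("ForeignMaterialAnchor", "Fremdmaterial"),
        lit(" "), slt("Side", c("links", "rechts"))),
    tpl("ForeignMaterial", c(1L, 3L, 4L, 5L), "neg",
        slt("Negation", "Kein"), lit(" "),
        slt("ForeignMaterialAnchor", "Fremdmaterial"),
        lit(" nachweisbar")),
    tpl("LymphNodes", 0:3, "neg",
        slt("Negation", "Keine"), lit(" "),
        slt("Suspicion", "suspekten"), lit(" "),
        slt("LymphNodeAnchor", "Lymphknoten"), lit(" "),
        slt("Side", "axillär beidseits")),
    tpl("LymphNodes", 4:6, "pos",
        slt("Suspicion", c("Suspekte", "Vergrößerte")), lit(" "),
        slt("LymphNodeAnchor", "Lymphknoten"), lit(" "),
        slt("Side", c("links axillär", "rechts axillär"))),
    tpl("Density", 0:6, "pos",
        slt("DensityAnchor", "ACR Typ"), lit(" "),
        slt("DensityClass", c("A", "B", "C", "D")), lit(" "),
        slt("Side", "beidseits")),
    tpl("AdditionalResult", 0:3, "neg",
        slt("Negation", c("Kein", "Sonst kein")), lit(" Anhalt für "),
        slt("MalignancyAnchor", "Malignität")),
    tpl("AdditionalResult", 4:6, "pos",
        lit("Weitere Abklärung bei Verdacht auf "),
        slt("MalignancyAnchor", "Malignität"), lit(" erforderlich")),
    tpl("Recommendation", c(0L, 3:6), "pos",
        slt("RecommendationAnchor", c("Kontrolle", "Verlaufskontrolle")),
        lit(" in "), slt("Interval", c("6 Monaten", "12 Monaten", "24 Monaten")),
        lit(" "), slt("Procedure", c("mammographisch", "sonographisch")),
        lit(" empfohlen")),
    tpl("BiradsStatement", 0:6, "pos",
        slt("BiradsAnchor", "BI-RADS"), lit(" "),
        slt("BiradsValue", as.character(0:6)), lit(" "),
        slt("Side", c("links", "rechts", "beidseits")))
  )
  class(bank) <- "ff_clause_bank"
  bank
}

# Render one template with given (or random) filler choices. Returns the
# clause text plus entity rows with 0-based offsets relative to the clause.
render_clause <- function(template, choices = NULL) {
  text <- ""
  e_type <- character(); e_start <- integer(); e_end <- integer()
  e_text <- character()
  for (part in template$parts) {
    if (!is.null(part$lit)) {
      text <- paste0(text, part$lit)
    } else {
      fill <- if (!is.null(choices) && !is.null(choices[[part$slot]])) {
        choices[[part$slot]]
      } else if (length(part$options) == 1L) {
        part$options
      } else {
        part$options[sample.int(length(part$options), 1L)]
      }
      start <- nchar(text)
      text <- paste0(text, fill)
      e_type <- c(e_type, part$slot); e_start <- c(e_start, start)
      e_end <- c(e_end, nchar(text)); e_text <- c(e_text, fill)
    }
  }
  list(text = text,
       entities = list(entity_type = e_type, start = e_start, end = e_end,
                       text = e_text),
       fact_type = template$fact_type)
}

#' Generator configuration
#'
#' @param reports_per_category Reports generated per BI-RADS category
#'   (default 3, giving 21 reports over categories 0-6).
#' @param categories BI-RADS categories to cover (default `0:6`).
#' @param fact_weights Named numeric vector scaling the inclusion probability
#'   of the optional clause types (`Asymmetry`, `ArchitecturalDistortion`,
#'   `ForeignMaterial`, second `BiradsStatement`); 1 keeps the default rates.
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @return An `ff_generator_config`.
#' @export
generator_config <- function(reports_per_category = 3L, categories = 0:6,
                             fact_weights = c(Asymmetry = 1,
                                              ArchitecturalDistortion = 1,
                                              ForeignMaterial = 1,
                                              BiradsStatement = 1),
                             seed = 20260101L) {
  stopifnot(length(categories) > 0L, all(categories %in% 0:6),
            reports_per_category >= 1L)
  structure(list(reports_per_category = as.integer(reports_per_category),
                 categories = as.integer(categories),
                 fact_weights = fact_weights,
                 seed = as.integer(seed)),
            class = "ff_generator_config")
}

pick_template <- function(bank, fact, cat, polarity = NULL) {
  hits <- Filter(function(t) {
    t$fact_type == fact && cat %in% t$cats &&
      (is.null(polarity) || t$polarity == polarity)
  }, bank)
  if (length(hits) == 0L) {
    stop(sprintf("clause bank has no template for fact '%s' in category %d",
                 fact, cat), call. = FALSE)
  }
  hits[[sample.int(length(hits), 1L)]]
}

wprob <- function(config, fact, base) {
  w <- config$fact_weights[fact]
  if (is.na(w)) w <- 1
  min(1, base * w)
}

gen_report_impl <- function(birads, config, bank, id) {
  clauses <- list()
  add <- function(template, choices = NULL) {
    clauses[[length(clauses) + 1L]] <<- render_clause(template, choices)
  }

  add(pick_template(bank, "PriorExams", birads,
                    if (stats::runif(1) < 0.5) "pos" else "neg"))
  add(pick_template(bank, "SkinFinding", birads))
  add(pick_template(bank, "MamillaRegion", birads))
  if (birads == 1L) {
    add(pick_template(bank, "Lesion", birads, "neg"))
  } else {
    add(pick_template(bank, "Lesion", birads, "pos"))
    add(pick_template(bank, "NippleDistance", birads))
  }
  calc_pol <- if (birads <= 1L) "neg" else if (birads >= 4L) "pos" else
    if (stats::runif(1) < 0.5) "pos" else "neg"
  add(pick_template(bank, "Calcification", birads, calc_pol))
  if (stats::runif(1) < wprob(config, "Asymmetry", 0.6)) {
    pol <- if (birads %in% c(0L, 4L, 5L)) "pos" else if (birads %in% 1:3) "neg" else NA
    if (!is.na(pol)) add(pick_template(bank, "Asymmetry", birads, pol))
  }
  if (stats::runif(1) < wprob(config, "ArchitecturalDistortion", 0.5)) {
    pol <- if (birads %in% 4:5) "pos" else if (birads %in% 1:3) "neg" else NA
    if (!is.na(pol)) add(pick_template(bank, "ArchitecturalDistortion", birads, pol))
  }
  if (birads == 6L) {
    add(pick_template(bank, "ForeignMaterial", birads, "pos"))
  } else if (birads %in% c(1L, 2L, 3L, 4L, 5L) &&
             stats::runif(1) < wprob(config, "ForeignMaterial", 0.5)) {
    add(pick_template(bank, "ForeignMaterial", birads))
  }
  add(pick_template(bank, "LymphNodes", birads))
  add(pick_template(bank, "Density", birads))
  add(pick_template(bank, "AdditionalResult", birads))
  if (birads %in% c(0L, 3L, 4L, 5L, 6L)) {
    add(pick_template(bank, "Recommendation", birads))
  }
  main_side <- sample(c("links", "rechts"), 1L)
  add(pick_template(bank, "BiradsStatement", birads),
      choices = list(BiradsValue = as.character(birads), Side = main_side))
  if (stats::runif(1) < wprob(config, "BiradsStatement", 0.5)) {
    other <- if (main_side == "links") "rechts" else "links"
    add(pick_template(bank, "BiradsStatement", birads),
        choices = list(BiradsValue = sample(c("1", "2"), 1L), Side = other))
  }

  findings <- ""
  facts <- list()
  for (cl in clauses) {
    offset <- nchar(findings)
    findings <- paste0(findings, cl$text, ". ")
    ents <- lapply(seq_along(cl$entities$entity_type), function(i) {
      entity_span(cl$entities$entity_type[i],
                  cl$entities$start[i] + offset,
                  cl$entities$end[i] + offset,
                  cl$entities$text[i])
    })
    facts[[length(facts) + 1L]] <-
      fact_instance(cl$fact_type, offset, offset + nchar(cl$text), ents)
  }
  findings <- sub(" $", "", findings)

  doc <- report_document(
    id = id, modality = "mammography",
    sections = list(
      indication = sprintf("Familiäre Belastung. Klinische Untersuchung Nr. %s. Frage nach Malignität.", id),
      findings = findings,
      assessment = sprintf("Beurteilung BI-RADS %d. Besprechung siehe Befund.", birads)),
    birads = birads)
  annotated_document(doc, facts)
}

#' Generate one synthetic annotated mammography report
#'
#' Assembles a findings section from category-appropriate clauses of the
#' clause bank and emits gold fact and entity spans with exact offsets; the
#' result always passes [validate_annotations()] against [demo_schema()]
#' with zero issues.
#'
#' @param birads BI-RADS category 0-6.
#' @param config An [generator_config()].
#' @param bank Clause bank (default [demo_clause_bank()]).
#' @param id Document id.
#' @param seed Optional integer seed (bit-reproducible output).
#' @return An [annotated_document()].
#' @export
generate_report <- function(birads, config = generator_config(),
                            bank = demo_clause_bank(), id = "synth-001",
                            seed = NULL) {
  stopifnot(birads %in% 0:6)
  if (!is.null(seed)) {
    with_seed(seed, gen_report_impl(as.integer(birads), config, bank, id))
  } else {
    gen_report_impl(as.integer(birads), config, bank, id)
  }
}

#' Generate a balanced synthetic annotated corpus
#'
#' @param reports_per_category Reports per BI-RADS category; overrides the
#'   config value when given.
#' @param config An [generator_config()].
#' @param seed Integer seed; overrides the config seed when given.
#' @param bank Clause bank.
#' @return List of [annotated_document()] objects of length
#'   `reports_per_category * length(categories)`, balanced across
#'   categories.
#' @export
generate_dataset <- function(reports_per_category = NULL,
                             config = generator_config(), seed = NULL,
                             bank = demo_clause_bank()) {
  npc <- reports_per_category %||% config$reports_per_category
  sd <- seed %||% config$seed
  with_seed(sd, {
    out <- list()
    i <- 0L
    for (cat in config$categories) {
      for (r in seq_len(npc)) {
        i <- i + 1L
        out[[i]] <- gen_report_impl(cat, config, bank,
                                    sprintf("synth-%03d", i))
      }
    }
    out
  })
}

#' Simulate a second annotator by perturbing gold annotations
#'
#' Projects the gold annotations to units at the requested level, then
#' jitters unit boundaries by up to `boundary_jitter_chars` characters
#' (clipped to the continuum with a warning), deletes units with probability
#' `deletion_prob`, and relabels units with probability `label_swap_prob`
#' (swapped to another category present at that level, when one exists).
#' With zero noise the perturbed unitization is identical to gold and
#' [unitizing_alpha()] is 1.
#'
#' @param gold An [annotated_document()].
#' @param noise List with `boundary_jitter_chars`, `deletion_prob`,
#'   `label_swap_prob` (all >= 0).
#' @param level `"fact"`, `"anchor"` or `"modifier"`.
#' @param schema Schema (default [demo_schema()]).
#' @param seed Integer seed.
#' @return List of two [unitization()] objects: `gold` and `perturbed`.
#' @export
perturb_annotations <- function(gold,
                                noise = list(boundary_jitter_chars = 0L,
                                             deletion_prob = 0,
                                             label_swap_prob = 0),
                                level = "fact", schema = demo_schema(),
                                seed = 1L) {
  jit <- as.integer(noise$boundary_jitter_chars %||% 0L)
  pdel <- noise$deletion_prob %||% 0
  pswap <- noise$label_swap_prob %||% 0
  stopifnot(jit >= 0L, pdel >= 0, pswap >= 0)
  base <- annotations_to_unitization(gold, level, schema, annotator = "gold")
  L <- base$length
  units <- base$units
  with_seed(seed, {
    keep <- stats::runif(nrow(units)) >= pdel
    units <- units[keep, , drop = FALSE]
    if (nrow(units) > 0L) {
      cats <- unique(units$category)
      clipped <- FALSE
      for (i in seq_len(nrow(units))) {
        if (jit > 0L) {
          s <- units$start[i] + sample(-jit:jit, 1L)
          e <- units$end[i] + sample(-jit:jit, 1L)
          if (s < 0L || e > L) clipped <- TRUE
          s <- max(0L, min(s, L - 1L))
          e <- max(s + 1L, min(e, L))
          units$start[i] <- s; units$end[i] <- e
        }
        if (pswap > 0 && stats::runif(1) < pswap && length(cats) > 1L) {
          units$category[i] <- sample(setdiff(cats, units$category[i]), 1L)
        }
      }
      if (clipped) warning("jittered unit clipped to continuum bounds")
      # jitter can create overlaps between neighbours; resolve by clipping
      # each unit's start to the previous unit's end
      units <- units[order(units$start, units$end), , drop = FALSE]
      if (nrow(units) > 1L) {
        drop <- logical(nrow(units))
        for (i in 2:nrow(units)) {
          prev_end <- max(units$end[seq_len(i - 1L)][!drop[seq_len(i - 1L)]],
                          0L)
          if (units$start[i] < prev_end) {
            if (prev_end >= units$end[i]) drop[i] <- TRUE
            else units$start[i] <- prev_end
          }
        }
        units <- units[!drop, , drop = FALSE]
      }
    }
    list(gold = base,
         perturbed = unitization("perturbed", L, units))
  })
}

#' Corrupt a clean corpus for curation testing
#'
#' Builds a raw record table from clean documents and injects exact
#' duplicates, reversible encoding garbles (the inverse of `encoding_map`)
#' and foreign-modality records, returning the ground-truth cleaning
#' statistics that [clean_corpus()] must recover. Garbles are applied only to
#' non-duplicated originals so every corruption count maps one-to-one to a
#' cleaning action; record order is originals, then duplicates, then foreign
#' records, so deduplication keeps the originals.
#'
#' @param documents List of [report_document()] or [annotated_document()]
#'   objects with pairwise distinct texts.
#' @param rates List with `duplicate_count`, `encoding_error_count`,
#'   `foreign_modality_count`.
#' @param seed Integer seed.
#' @param encoding_map Repair map whose inverse garbles the text
#'   (default [default_encoding_map()]).
#' @return List with `records` (data frame: `id`, `modality`, `birads`,
#'   section columns) and `stats`, the expected `ff_cleaning_stats`.
#' @export
corrupt_corpus <- function(documents,
                           rates = list(duplicate_count = 0L,
                                        encoding_error_count = 0L,
                                        foreign_modality_count = 0L),
                           seed = 1L,
                           encoding_map = default_encoding_map()) {
  docs <- lapply(documents, function(d) if (inherits(d, "ff_annotated_doc")) d$document else d)
  n <- length(docs)
  ndup <- as.integer(rates$duplicate_count %||% 0L)
  nenc <- as.integer(rates$encoding_error_count %||% 0L)
  nfor <- as.integer(rates$foreign_modality_count %||% 0L)
  stopifnot(ndup >= 0L, nenc >= 0L, nfor >= 0L)

  rec_of <- function(d, id = d$id, modality = d$modality) {
    data.frame(id = id, modality = modality,
               birads = if (is.na(d$birads)) NA_integer_ else d$birads,
               indication = d$sections$indication %||% NA_character_,
               findings = d$sections$findings %||% NA_character_,
               assessment = d$sections$assessment %||% NA_character_,
               stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, lapply(docs, rec_of))

  garble <- function(x) {
    for (i in seq_along(encoding_map)) {
      x <- gsub(encoding_map[[i]], names(encoding_map)[i], x, fixed = TRUE)
    }
    x
  }
  with_seed(seed, {
    garbleable <- which(vapply(seq_len(n), function(i) {
      any(vapply(c("indication", "findings", "assessment"), function(col) {
        v <- records[[col]][i]
        !is.na(v) && garble(v) != v
      }, TRUE))
    }, TRUE))
    if (nenc > length(garbleable)) {
      stop(sprintf("only %d documents contain garbleable characters, need %d",
                   length(garbleable), nenc), call. = FALSE)
    }
    enc_idx <- sort(sample(garbleable, nenc))

    clean_pool <- setdiff(seq_len(n), enc_idx)
    if (ndup > 0L && length(clean_pool) == 0L) {
      stop("no ungarbled documents available to duplicate", call. = FALSE)
    }
    dup_src <- if (ndup > 0L) sample(clean_pool, ndup, replace = TRUE) else integer()

    dup_records <- if (ndup > 0L) {
      dr <- records[dup_src, , drop = FALSE]
      dr$id <- sprintf("dup-%04d", seq_len(ndup))
      dr
    } else NULL

    for (col in c("indication", "findings", "assessment")) {
      v <- records[[col]][enc_idx]
      records[[col]][enc_idx] <- ifelse(is.na(v), v, garble(v))
    }

    foreign_records <- if (nfor > 0L) {
      data.frame(id = sprintf("ct-%04d", seq_len(nfor)),
                 modality = "ct",
                 birads = NA_integer_,
                 indication = "Staging.",
                 findings = sprintf("Computertomographie des Thorax Untersuchung Nr. %d. Unauffaelliger Befund der Lunge.", seq_len(nfor)),
                 assessment = "Kein Nachweis von Metastasen.",
                 stringsAsFactors = FALSE)
    } else NULL

    out <- rbind(records, dup_records, foreign_records)
    rownames(out) <- NULL
    stats <- structure(list(n_input = nrow(out), n_encoding_fixed = nenc,
                            n_duplicates_removed = ndup,
                            n_nonmodality_removed = nfor,
                            n_output = n),
                       class = "ff_cleaning_stats")
    list(records = out, stats = stats)
  })
}
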
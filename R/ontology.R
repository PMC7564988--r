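#' Construct an entity slot
#'
#' An entity slot declares one typed span category that can occur inside an
#' utterance, for example `vital-type` or `start-time`. Slots come in two
#' kinds: `activity` slots hold the activity-class object that completes an
#' action verb (the head of the utterance), and `record` slots hold the
#' recorded details attached through prepositional phrases (values, places,
#' times, targets).
#'
#' @param name Slot identifier, lower-case hyphenated (e.g. `"vital-type"`).
#' @param kind Either `"activity"` or `"record"`.
#' @param values Character vector of surface strings the slot can take.
#' @param synonyms Optional named list mapping a surface string in `values`
#'   to a character vector of interchangeable alternatives.
#' @return An object of class `entity_slot`.
#' @export
entity_slot <- function(name, kind = c("activity", "record"), values,
                        synonyms = list()) {
  kind <- match.arg(kind)
  structure(
    list(name = as.character(name), kind = kind,
         values = as.character(values), synonyms = synonyms),
    class = "entity_slot"
  )
}

#' Construct a prepositional phrase template
#'
#' Phrase templates are the shuffleable units of an utterance: a preposition
#' followed by an entity placeholder, optionally with one modifier drawn
#' from `modifiers` between them. Pattern 1 is preposition + placeholder;
#' pattern 2 is preposition + modifier + placeholder.
#'
#' @param preposition Preposition string (may be `""`).
#' @param slot Name of the entity slot filling the placeholder.
#' @param modifiers Character vector of alternative modifiers (pattern 2)
#'   or empty (pattern 1).
#' @param pattern 1 or 2; defaults to 2 when modifiers are given.
#' @return An object of class `phrase_template`.
#' @export
phrase_template <- function(preposition, slot, modifiers = character(),
                            pattern = if (length(modifiers)) 2L else 1L) {
  structure(
    list(preposition = as.character(preposition),
         modifiers = as.character(modifiers),
         slot = as.character(slot), pattern = as.integer(pattern)),
    class = "phrase_template"
  )
}

#' Construct an intent specification
#'
#' An intent is an action verb plus an activity class (e.g. `add-vital`,
#' `clean-oral`). Its utterances are rendered as
#' verb + activity value + record phrases.
#'
#' @param name Intent identifier.
#' @param verbs Non-empty character vector of action verbs (multi-word verbs
#'   such as `"help to use"` are allowed).
#' @param activity_slot Name of the activity-kind slot providing the object
#'   of the verb.
#' @param record_templates List of [phrase_template()] objects referencing
#'   record-kind slots.
#' @return An object of class `intent_spec`.
#' @export
intent_spec <- function(name, verbs, activity_slot, record_templates = list()) {
  structure(
    list(name = as.character(name), verbs = as.character(verbs),
         activity_slot = as.character(activity_slot),
         record_templates = record_templates),
    class = "intent_spec"
  )
}

#' Construct an ontology
#'
#' @param intents List of [intent_spec()] objects.
#' @param slots List of [entity_slot()] objects.
#' @param version Schema/content version string.
#' @return An object of class `ontology`.
#' @seealso [validate_ontology()], [load_ontology()], [builtin_fixture()]
#' @export
ontology <- function(intents, slots, version = "1.0") {
  structure(
    list(version = as.character(version), slots = slots, intents = intents),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> version", x$version, "\n")
  cat(" ", length(x$intents), "intents:",
      paste(vapply(x$intents, `[[`, "", "name"), collapse = ", "), "\n")
  cat(" ", length(x$slots), "slots:",
      paste(vapply(x$slots, `[[`, "", "name"), collapse = ", "), "\n")
  invisible(x)
}

ontology_slot <- function(o, name) {
  for (s in o$slots) if (s$name == name) return(s)
  NULL
}

ontology_intent <- function(o, name) {
  for (i in o$intents) if (i$name == name) return(i)
  NULL
}

# All surface options for a slot: declared values plus their synonyms.
slot_options <- function(slot) {
  unique(c(slot$values, unlist(slot$synonyms, use.names = FALSE)))
}

#' Validate an ontology
#'
#' Checks every structural invariant of the data model and returns the
#' violations as data rather than raising: unique intent and slot names,
#' non-empty verb and value inventories, resolvable slot references,
#' activity/record kind agreement, phrase pattern consistency, and synonym
#' keys that are declared values.
#'
#' @param o An [ontology()] object.
#' @return Character vector of human-readable issues; empty iff valid.
#' @export
validate_ontology <- function(o) {
  issues <- character()
  say <- function(...) issues[[length(issues) + 1L]] <<- sprintf(...)

  if (!length(o$intents)) say("ontology declares no intents")

  slot_names <- vapply(o$slots, `[[`, "", "name")
  for (nm in unique(slot_names[duplicated(slot_names)])) {
    say("duplicate slot name '%s'", nm)
  }
  for (s in o$slots) {
    if (!length(s$values)) say("slot '%s' has no values", s$name)
    if (!s$kind %in% c("activity", "record")) {
      say("slot '%s' has unknown kind '%s'", s$name, s$kind)
    }
    bad <- setdiff(names(s$synonyms), s$values)
    for (key in bad) {
      say("slot '%s': synonym key '%s' is not a declared value", s$name, key)
    }
  }

  intent_names <- vapply(o$intents, `[[`, "", "name")
  for (nm in unique(intent_names[duplicated(intent_names)])) {
    say("duplicate intent name '%s'", nm)
  }
  for (it in o$intents) {
    if (!length(it$verbs)) say("intent '%s' has no verbs", it$name)
    act <- ontology_slot(o, it$activity_slot)
    if (is.null(act)) {
      say("intent '%s' references undeclared activity slot '%s'",
          it$name, it$activity_slot)
    } else if (act$kind != "activity") {
      say("intent '%s': activity slot '%s' has kind '%s', expected 'activity'",
          it$name, act$name, act$kind)
    }
    seen <- character()
    for (tpl in it$record_templates) {
      ref <- ontology_slot(o, tpl$slot)
      if (is.null(ref)) {
        say("intent '%s': template references undeclared slot '%s'",
            it$name, tpl$slot)
      } else if (ref$kind != "record") {
        say("intent '%s': template slot '%s' has kind '%s', expected 'record'",
            it$name, ref$name, ref$kind)
      }
      if (tpl$slot %in% seen) {
        say("intent '%s': duplicate template reference to slot '%s'",
            it$name, tpl$slot)
      }
      seen <- c(seen, tpl$slot)
      if (tpl$pattern == 1L && length(tpl$modifiers)) {
        say("intent '%s': pattern-1 template on slot '%s' must have no modifiers",
            it$name, tpl$slot)
      }
      if (tpl$pattern == 2L && !length(tpl$modifiers)) {
        say("intent '%s': pattern-2 template on slot '%s' has empty modifiers",
            it$name, tpl$slot)
      }
      if (!tpl$pattern %in% c(1L, 2L)) {
        say("intent '%s': template on slot '%s' has invalid pattern %s",
            it$name, tpl$slot, tpl$pattern)
      }
    }
  }
  issues
}

slot_from_list <- function(x) {
  entity_slot(
    name = x$name,
    kind = x$kind,
    values = unlist(x$values),
    synonyms = if (is.null(x$synonyms)) list() else
      lapply(x$synonyms, function(v) as.character(unlist(v)))
  )
}

template_from_list <- function(x) {
  mods <- if (is.null(x$modifiers)) character() else as.character(unlist(x$modifiers))
  phrase_template(
    preposition = if (is.null(x$preposition)) "" else x$preposition,
    slot = x$slot,
    modifiers = mods,
    pattern = if (is.null(x$pattern)) {
      if (length(mods)) 2L else 1L
    } else {
      as.integer(x$pattern)
    }
  )
}

intent_from_list <- function(x) {
  intent_spec(
    name = x$name,
    verbs = as.character(unlist(x$verbs)),
    activity_slot = x$activity_slot,
    record_templates = lapply(x$record_templates, template_from_list)
  )
}

#' Load an ontology from a YAML file
#'
#' The config schema is a single YAML document with top-level keys
#' `version`, `slots` and `intents`; see the packaged
#' `extdata/nursing_ontology.yaml` for a complete example and the package
#' vignette for the schema reference.
#'
#' @param path Path to a YAML ontology file.
#' @return A validated [ontology()] object.
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("ontology format error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(doc$slots) || is.null(doc$intents)) {
    stop("ontology format error in '", path,
         "': missing required keys 'slots' and/or 'intents'", call. = FALSE)
  }
  o <- ontology(
    intents = lapply(doc$intents, intent_from_list),
    slots = lapply(doc$slots, slot_from_list),
    version = if (is.null(doc$version)) "1.0" else as.character(doc$version)
  )
  issues <- validate_ontology(o)
  if (length(issues)) {
    stop("ontology validation failed for '", path, "':\n  ",
         paste(issues, collapse = "\n  "), call. = FALSE)
  }
  o
}

#' Write an ontology to a YAML file
#'
#' Inverse of [load_ontology()]: a written file re-loads to a structurally
#' equal ontology.
#'
#' @param o An [ontology()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(o, path) {
  doc <- list(
    version = o$version,
    slots = lapply(o$slots, function(s) {
      out <- list(name = s$name, kind = s$kind, values = as.list(s$values))
      if (length(s$synonyms)) out$synonyms <- lapply(s$synonyms, as.list)
      out
    }),
    intents = lapply(o$intents, function(it) {
      list(
        name = it$name,
        verbs = as.list(it$verbs),
        activity_slot = it$activity_slot,
        record_templates = lapply(it$record_templates, function(tpl) {
          out <- list(preposition = tpl$preposition, slot = tpl$slot,
                      pattern = tpl$pattern)
          if (length(tpl$modifiers)) out$modifiers <- as.list(tpl$modifiers)
          out
        })
      )
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Built-in nursing-care fixture ontology
#'
#' A deterministic six-intent nursing-care ontology (vital-sign recording,
#' oral care, toilet assistance, meal preparation, bathing assistance and
#' diaper change) with per-intent activity slots, record slots, and the
#' shared record slots `start-time`, `stop-time` and `target`. It ships with
#' the package so the full pipeline is runnable and testable offline.
#'
#' @return A validated [ontology()] object; identical across calls.
#' @export
builtin_fixture <- function() {
  path <- system.file("extdata", "nursing_ontology.yaml",
                      package = "dialogforge", mustWork = TRUE)
  load_ontology(path)
}
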
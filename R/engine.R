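# Trigger definitions, registries and cohort screening.

#' Define a trigger
#'
#' A trigger couples a screening predicate with a suspect-drug query: the
#' predicate decides whether the clue fires; the suspect query names the
#' exposure classes a reviewer should examine, attached to every hit for
#' adjudication. In `"strict"` evaluation mode the hit is kept only when a
#' suspect exposure co-occurs.
#'
#' @param trigger_id Identifier (for example `"L1"`, `"S3"`, `"GTT-M4"`).
#' @param module One of `"laboratory"`, `"medication"`, `"symptom"`,
#'   `"outcome"`.
#' @param name Short human-readable description.
#' @param predicate A [predicate node][predicate_nodes].
#' @param suspect_classes Drug classes of the suspect-exposure query; the
#'   sentinel `"any"` matches every exposure.
#' @param active Inactive triggers are skipped by [screen_cohort()].
#' @param provenance Free-text source note.
#' @return A list of class `trigger_definition`.
#' @export
trigger_def <- function(trigger_id, module, name, predicate,
                        suspect_classes = character(), active = TRUE,
                        provenance = "study") {
  stopifnot(module %in% c("laboratory", "medication", "symptom", "outcome"))
  structure(list(trigger_id = trigger_id, module = module, name = name,
                 predicate = predicate, suspect_classes = suspect_classes,
                 active = active, provenance = provenance),
            class = "trigger_definition")
}

#' Assemble a trigger registry
#'
#' @param name Registry name.
#' @param version Version string.
#' @param triggers List of [trigger_def()] objects; ids must be unique.
#' @param lookback_hours Window used when attaching suspect exposures: an
#'   exposure co-occurs with a finding at time `t` iff
#'   `start <= t < stop + lookback_hours`.
#' @return A list of class `trigger_registry`.
#' @export
trigger_registry <- function(name, version, triggers, lookback_hours = 48) {
  ids <- vapply(triggers, `[[`, "", "trigger_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate trigger_id in registry: ", dup[[1]], call. = FALSE)
  }
  structure(list(name = name, version = version, triggers = triggers,
                 lookback_hours = lookback_hours),
            class = "trigger_registry")
}

#' @export
print.trigger_registry <- function(x, ...) {
  mods <- table(vapply(x$triggers, `[[`, "", "module"))
  cat(sprintf("<trigger_registry> %s (v%s): %d triggers [%s]\n",
              x$name, x$version, length(x$triggers),
              paste(names(mods), mods, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Tabulate a registry
#' @param registry A `trigger_registry`.
#' @return A tibble with one row per trigger.
#' @export
registry_tibble <- function(registry) {
  tibble::tibble(
    trigger_id = vapply(registry$triggers, `[[`, "", "trigger_id"),
    module = vapply(registry$triggers, `[[`, "", "module"),
    name = vapply(registry$triggers, `[[`, "", "name"),
    suspect_classes = vapply(registry$triggers, function(t) {
      paste(t$suspect_classes, collapse = ";")
    }, ""),
    active = vapply(registry$triggers, `[[`, TRUE, "active"),
    provenance = vapply(registry$triggers, `[[`, "", "provenance")
  )
}

empty_hits <- function() {
  tibble::tibble(record_id = character(), trigger_id = character(),
                 time = numeric(), evidence_ids = list(),
                 suspect_exposure_ids = list())
}

#' Evaluate one trigger against one record
#'
#' One hit is emitted per distinct qualifying finding, capped at one hit per
#' trigger per record per calendar day (repeated measurements of the same
#' abnormality are chart-review duplicates, not new clues). In `"screening"`
#' mode the predicate alone fires and matching suspect exposures are
#' attached when present; in `"strict"` mode hits without a co-occurring
#' suspect exposure are dropped.
#'
#' @param definition A [trigger_def()].
#' @param record A validated `patient_record`.
#' @param mode `"screening"` (default) or `"strict"`.
#' @param lookback_hours Suspect co-occurrence window (from the registry).
#' @return A tibble of hits (possibly empty) with columns `record_id`,
#'   `trigger_id`, `time`, `evidence_ids` (list), `suspect_exposure_ids`
#'   (list).
#' @export
evaluate_trigger <- function(definition, record, mode = c("screening", "strict"),
                             lookback_hours = 48) {
  mode <- match.arg(mode)
  idx <- index_record(record)
  hits_tibble(list(evaluate_trigger_idx(definition, idx, mode, lookback_hours)))
}

# hot path: returns NULL or a plain list of parallel vectors; the tibble is
# assembled once per screening run by hits_tibble()
evaluate_trigger_idx <- function(definition, idx, mode, lookback_hours) {
  r <- eval_node(definition$predicate, idx)
  if (is_guard_result(r)) {
    stop("trigger ", definition$trigger_id,
         ": predicate root must yield findings, not a guard", call. = FALSE)
  }
  if (!length(r$times)) return(NULL)
  ord <- order(r$times)
  times <- r$times[ord]
  evid <- r$evidence[ord]
  # cap: one hit per calendar day
  keep <- !duplicated(floor(times / 24))
  times <- times[keep]
  evid <- evid[keep]
  suspects <- lapply(times, function(t) {
    if (!length(definition$suspect_classes)) return(character())
    if ("any" %in% definition$suspect_classes) {
      sel <- idx$exp_start <= t & t < idx$exp_stop + lookback_hours
    } else {
      cls <- vapply(idx$exp_classes, function(cl) {
        length(intersect(cl, definition$suspect_classes)) > 0
      }, FALSE)
      sel <- cls & idx$exp_start <= t & t < idx$exp_stop + lookback_hours
    }
    idx$exp_ids[sel]
  })
  if (mode == "strict") {
    keep <- lengths(suspects) > 0
    times <- times[keep]; evid <- evid[keep]; suspects <- suspects[keep]
    if (!length(times)) return(NULL)
  }
  list(record_id = rep(idx$rec$record_id, length(times)),
       trigger_id = rep(definition$trigger_id, length(times)),
       time = times, evidence_ids = evid, suspect_exposure_ids = suspects)
}

hits_tibble <- function(rows) {
  rows <- rows[!vapply(rows, is.null, FALSE)]
  if (!length(rows)) return(empty_hits())
  tibble::tibble(
    record_id = unlist(lapply(rows, `[[`, "record_id")),
    trigger_id = unlist(lapply(rows, `[[`, "trigger_id")),
    time = unlist(lapply(rows, `[[`, "time")),
    evidence_ids = do.call(c, lapply(rows, `[[`, "evidence_ids")),
    suspect_exposure_ids = do.call(c, lapply(rows, `[[`, "suspect_exposure_ids"))
  )
}

#' Screen a cohort with a trigger registry
#'
#' Evaluates every active trigger against every record. Output is
#' deterministic: rows are sorted by `(record_id, trigger_id, time)` and are
#' independent of record order or of the ordering of a record's internal
#' lists. A record whose evaluation fails (for example an event missing an
#' attribute required by a predicate) contributes no hits; the failure is
#' raised as a warning and listed in the run report attached as the
#' `"report"` attribute.
#'
#' @param registry A [trigger_registry()].
#' @param cohort A list of validated `patient_record`s.
#' @param mode `"screening"` or `"strict"` (see [evaluate_trigger()]).
#' @return A hit tibble (see [evaluate_trigger()]); attribute `"report"`
#'   holds a tibble of per-record evaluation errors.
#' @export
screen_cohort <- function(registry, cohort, mode = c("screening", "strict")) {
  mode <- match.arg(mode)
  active <- Filter(function(t) isTRUE(t$active), registry$triggers)
  out <- vector("list", length(cohort))
  errs <- list()
  for (i in seq_along(cohort)) {
    idx <- index_record(cohort[[i]])
    res <- tryCatch(
      lapply(active, evaluate_trigger_idx, idx = idx, mode = mode,
             lookback_hours = registry$lookback_hours),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning(sprintf("screening failed for record '%s': %s",
                      cohort[[i]]$record_id, conditionMessage(res)),
              call. = FALSE)
      errs[[length(errs) + 1]] <- tibble::tibble(
        record_id = cohort[[i]]$record_id, error = conditionMessage(res))
    } else {
      out[[i]] <- res
    }
  }
  hits <- hits_tibble(unlist(out, recursive = FALSE))
  hits <- hits[order(hits$record_id, hits$trigger_id, hits$time), ]
  attr(hits, "report") <- if (length(errs)) dplyr::bind_rows(errs) else
    tibble::tibble(record_id = character(), error = character())
  hits
}

#' Per-trigger hit counts
#'
#' Aggregates a hit table to one row per trigger in the registry, including
#' zero-count rows.
#'
#' @param hits Hit tibble from [screen_cohort()].
#' @param registry The registry that produced the hits.
#' @return Tibble of `trigger_id`, `module`, `n_hits`, `n_records`.
#' @export
hit_counts <- function(hits, registry) {
  ids <- vapply(registry$triggers, `[[`, "", "trigger_id")
  mods <- vapply(registry$triggers, `[[`, "", "module")
  tibble::tibble(
    trigger_id = ids,
    module = mods,
    n_hits = vapply(ids, function(id) sum(hits$trigger_id == id), 0L),
    n_records = vapply(ids, function(id) {
      length(unique(hits$record_id[hits$trigger_id == id]))
    }, 0L)
  )
}

#' Export a hit table to CSV
#'
#' List columns are flattened with `;` separators.
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @export
write_hits_csv <- function(hits, path) {
  df <- data.frame(
    record_id = hits$record_id,
    trigger_id = hits$trigger_id,
    time = hits$time,
    evidence_ids = vapply(hits$evidence_ids, paste, "", collapse = ";"),
    suspect_exposure_ids = vapply(hits$suspect_exposure_ids, paste, "",
                                  collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- registry serialization ---------------------------------------------

strip_predicate <- function(node) {
  node <- unclass(node)
  node <- node[!vapply(node, is.null, FALSE)]
  if (!is.null(node$children)) {
    node$children <- lapply(node$children, strip_predicate)
  }
  node
}

restore_predicate <- function(node) {
  if (!is.null(node$children)) {
    node$children <- lapply(node$children, restore_predicate)
  }
  if (!is.null(node$attr_any)) {
    node$attr_any <- lapply(node$attr_any, function(a) a)
  }
  structure(node, class = "trigger_predicate")
}

#' Write a registry to a YAML file
#' @param registry A `trigger_registry`.
#' @param path Output path.
#' @seealso [load_registry()]
#' @export
write_registry <- function(registry, path) {
  obj <- list(
    name = registry$name, version = registry$version,
    lookback_hours = registry$lookback_hours,
    triggers = lapply(registry$triggers, function(t) {
      list(trigger_id = t$trigger_id, module = t$module, name = t$name,
           predicate = strip_predicate(t$predicate),
           suspect_classes = as.list(t$suspect_classes),
           active = t$active, provenance = t$provenance)
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a trigger registry
#'
#' Built-in names: `"obstetric_39"` (the 39-item obstetric registry:
#' 12 laboratory, 9 medication, 14 symptom, 4 outcome triggers),
#' `"gtt_medication"` (the 13-rule IHI Global Trigger Tool medication-module
#' comparator) and `"revised_35"` (the obstetric registry after the
#' post-review revision, see [refine_registry()]). Any other string is
#' treated as a path to a YAML registry file written by [write_registry()].
#'
#' @param name Built-in registry name or file path.
#' @return A validated `trigger_registry`.
#' @export
load_registry <- function(name) {
  if (name %in% c("obstetric_39", "gtt_medication", "revised_35")) {
    return(switch(name,
                  obstetric_39 = obstetric_registry(),
                  gtt_medication = gtt_registry(),
                  revised_35 = revised_registry()))
  }
  if (!file.exists(name)) {
    stop("not a built-in registry and file does not exist: ", name,
         call. = FALSE)
  }
  obj <- yaml::read_yaml(name)
  trig <- lapply(obj$triggers, function(t) {
    if (is.null(t$trigger_id) || is.null(t$module) || is.null(t$predicate)) {
      stop(sprintf("malformed registry rule '%s': trigger_id, module and predicate are required",
                   if (is.null(t$trigger_id)) "?" else t$trigger_id),
           call. = FALSE)
    }
    trigger_def(t$trigger_id, t$module,
                if (is.null(t$name)) t$trigger_id else t$name,
                restore_predicate(t$predicate),
                unlist(t$suspect_classes) %||% character(),
                if (is.null(t$active)) TRUE else t$active,
                if (is.null(t$provenance)) "file" else t$provenance)
  })
  trigger_registry(obj$name, obj$version, trig,
                   if (is.null(obj$lookback_hours)) 48 else obj$lookback_hours)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
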
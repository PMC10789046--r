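# Declarative trigger predicate trees.
#
# A predicate is a list-shaped node tree. Leaf kinds read one slice of the
# record (labs by analyte, events by code, exposures by class); composite
# kinds combine children. Leaves yield *matches* — qualifying findings with a
# time and evidence ids — while guard kinds yield a record-level boolean.
# Thresholds carry a unit and are compared in the analyte's canonical unit.

pred_node <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "trigger_predicate")
}

#' Predicate node constructors
#'
#' Build the declarative rule tree evaluated by [evaluate_trigger()].
#'
#' * `pred_lab()` — a lab threshold over one or more analytes
#'   (`cmp` one of `"<" ">" "<=" ">=" "between"`; `threshold` in `unit`,
#'   converted to the analyte's canonical unit at evaluation).
#'   `requires_status` restricts to a diabetic status, `requires_class` to
#'   records carrying an exposure with one of the given classes,
#'   `exclude_flags` vetoes records carrying a comorbidity flag.
#' * `pred_event()` — a clinical event by code; `attr_any` is a list of
#'   `list(attr, cmp, value)` alternatives, at least one of which must be
#'   satisfied (an event carrying none of the named attributes is an
#'   evaluation error); `exclude_flags` vetoes flagged events and flagged
#'   records; `source` selects maternal events, neonate events or both.
#' * `pred_drug()` — a medication exposure by class, optionally filtered by
#'   `route` or `abrupt_stop`.
#' * `pred_drug_after_event()` — an exposure starting within `window_h`
#'   hours after a qualifying event (antidote-style rules).
#' * `pred_drug_after_drug()` — an exposure starting during, or within
#'   `window_h` hours after, a prior exposure of another class.
#' * `pred_aki()` — the three-branch acute kidney injury screen
#'   ([aki_rule()]) over the record's creatinine and urine-output series.
#' * `pred_liver()` — the R-ratio liver-injury screen ([liver_injury_rule()])
#'   over paired ALT/ALP results.
#' * `pred_all()`, `pred_any()`, `pred_not()` — conjunction (matches come
#'   from the first match-yielding child), disjunction, and negation-guard.
#' * `pred_guard()` — record-level guard (`delivery_mode_not`,
#'   `delivery_mode_in`, `requires_class`, `requires_status`).
#'
#' @param analytes,cmp,threshold,threshold_high,unit,requires_status,requires_class,exclude_flags
#'   Lab-threshold parameters.
#' @param codes,source,attr_any Event parameters.
#' @param classes,route,abrupt_stop Exposure parameters.
#' @param event_codes,prior_classes,window_h Sequence parameters.
#' @param ... Child nodes for `pred_all()` / `pred_any()`.
#' @param child Child node for `pred_not()`.
#' @param delivery_mode_not,delivery_mode_in Guard parameters.
#' @return A `trigger_predicate` node.
#' @name predicate_nodes
NULL

#' @rdname predicate_nodes
#' @export
pred_lab <- function(analytes, cmp, threshold, unit,
                     threshold_high = NULL, requires_status = NULL,
                     requires_class = NULL, exclude_flags = character()) {
  pred_node("lab_threshold", analytes = analytes, cmp = cmp,
            threshold = threshold, threshold_high = threshold_high,
            unit = unit, requires_status = requires_status,
            requires_class = requires_class, exclude_flags = exclude_flags)
}

#' @rdname predicate_nodes
#' @export
pred_event <- function(codes, source = "events", attr_any = list(),
                       exclude_flags = character()) {
  pred_node("event", codes = codes, source = source, attr_any = attr_any,
            exclude_flags = exclude_flags)
}

#' @rdname predicate_nodes
#' @export
pred_drug <- function(classes, route = NULL, abrupt_stop = NULL) {
  pred_node("drug", classes = classes, route = route, abrupt_stop = abrupt_stop)
}

#' @rdname predicate_nodes
#' @export
pred_drug_after_event <- function(classes, event_codes, window_h = 48,
                                  route = NULL, exclude_flags = character()) {
  pred_node("drug_after_event", classes = classes, event_codes = event_codes,
            window_h = window_h, route = route, exclude_flags = exclude_flags)
}

#' @rdname predicate_nodes
#' @export
pred_drug_after_drug <- function(classes, prior_classes, window_h = 48,
                                 route = NULL) {
  pred_node("drug_after_drug", classes = classes, prior_classes = prior_classes,
            window_h = window_h, route = route)
}

#' @rdname predicate_nodes
#' @export
pred_aki <- function() pred_node("aki")

#' @rdname predicate_nodes
#' @export
pred_liver <- function(window_h = 48) pred_node("liver", window_h = window_h)

#' @rdname predicate_nodes
#' @export
pred_all <- function(...) pred_node("all", children = list(...))

#' @rdname predicate_nodes
#' @export
pred_any <- function(...) pred_node("any", children = list(...))

#' @rdname predicate_nodes
#' @export
pred_not <- function(child) pred_node("not", children = list(child))

#' @rdname predicate_nodes
#' @export
pred_guard <- function(delivery_mode_not = NULL, delivery_mode_in = NULL,
                       requires_class = NULL, requires_status = NULL) {
  pred_node("guard", delivery_mode_not = delivery_mode_not,
            delivery_mode_in = delivery_mode_in,
            requires_class = requires_class,
            requires_status = requires_status)
}

# ---- record index --------------------------------------------------------

# Precomputed per-record view used by the evaluator; built once per record
# per screening run. Plain vectors, not data frames: the evaluator sits in
# the innermost loop of cohort screening.
index_record <- function(rec) {
  labs <- rec$labs
  lab_df <- list(
    lab_id = vapply(labs, `[[`, "", "lab_id"),
    analyte = vapply(labs, `[[`, "", "analyte"),
    value = vapply(labs, function(l) to_canonical(l$value, l$analyte, l$unit), 0),
    time = vapply(labs, `[[`, 0, "time"),
    is_baseline = vapply(labs, `[[`, FALSE, "is_baseline")
  )
  ev_index <- function(evs) {
    list(
      ids = vapply(evs, `[[`, "", "event_id"),
      codes = vapply(evs, `[[`, "", "code"),
      times = vapply(evs, `[[`, 0, "time"),
      attrs = lapply(evs, `[[`, "attributes"),
      flags = lapply(evs, `[[`, "exclusion_flags")
    )
  }
  list(
    rec = rec,
    labs = lab_df,
    exp_ids = vapply(rec$exposures, `[[`, "", "exposure_id"),
    exp_classes = lapply(rec$exposures, `[[`, "drug_classes"),
    exp_start = vapply(rec$exposures, `[[`, 0, "start_time"),
    exp_stop = vapply(rec$exposures, `[[`, 0, "stop_time"),
    exp_route = vapply(rec$exposures, `[[`, "", "route"),
    exp_abrupt = vapply(rec$exposures, `[[`, FALSE, "abrupt_stop"),
    ev = ev_index(rec$events),
    nev = ev_index(rec$neonate_events)
  )
}

no_matches <- function() {
  list(times = numeric(), evidence = list())
}

matches <- function(times, evidence) {
  list(times = times, evidence = evidence)
}

apply_cmp <- function(x, cmp, lo, hi = NULL) {
  switch(cmp,
    "<" = x < lo,
    ">" = x > lo,
    "<=" = x <= lo,
    ">=" = x >= lo,
    "between" = x >= lo & x <= hi,
    stop("unknown comparator: ", cmp, call. = FALSE)
  )
}

record_has_class <- function(idx, classes) {
  any(vapply(idx$exp_classes, function(cl) length(intersect(cl, classes)) > 0,
             FALSE))
}

# ---- evaluation ----------------------------------------------------------

# Returns either list(times, evidence) for match-yielding nodes or a single
# logical for guard nodes.
eval_node <- function(node, idx) {
  switch(node$kind,
    lab_threshold = eval_lab(node, idx),
    event = eval_event(node, idx),
    drug = eval_drug(node, idx),
    drug_after_event = eval_drug_after_event(node, idx),
    drug_after_drug = eval_drug_after_drug(node, idx),
    aki = eval_aki(node, idx),
    liver = eval_liver(node, idx),
    all = eval_all(node, idx),
    any = eval_any(node, idx),
    not = eval_not(node, idx),
    guard = eval_guard(node, idx),
    stop("unknown predicate kind: ", node$kind, call. = FALSE)
  )
}

is_guard_result <- function(x) is.logical(x)

eval_lab <- function(node, idx) {
  rec <- idx$rec
  if (!is.null(node$requires_status) &&
      !identical(rec$diabetic_status, node$requires_status)) {
    return(no_matches())
  }
  if (!is.null(node$requires_class) && !record_has_class(idx, node$requires_class)) {
    return(no_matches())
  }
  if (length(node$exclude_flags) &&
      length(intersect(rec$comorbidity_flags, node$exclude_flags))) {
    return(no_matches())
  }
  labs <- idx$labs
  times <- numeric(); evid <- list()
  # thresholds are stated in node$unit; convert to canonical per analyte
  for (a in node$analytes) {
    sel <- which(labs$analyte == a)
    if (!length(sel)) next
    lo <- to_canonical(node$threshold, a, node$unit)
    hi <- if (!is.null(node$threshold_high)) {
      to_canonical(node$threshold_high, a, node$unit)
    } else NULL
    keep <- sel[apply_cmp(labs$value[sel], node$cmp, lo, hi)]
    if (length(keep)) {
      times <- c(times, labs$time[keep])
      evid <- c(evid, as.list(labs$lab_id[keep]))
    }
  }
  matches(times, evid)
}

eval_event <- function(node, idx) {
  rec <- idx$rec
  srcs <- switch(node$source,
                 events = list(idx$ev),
                 neonate_events = list(idx$nev),
                 both = list(idx$ev, idx$nev))
  if (length(node$exclude_flags) &&
      length(intersect(rec$comorbidity_flags, node$exclude_flags))) {
    return(no_matches())
  }
  times <- numeric(); evid <- list()
  for (src in srcs) {
    sel <- which(src$codes %in% node$codes)
    for (i in sel) {
      if (length(intersect(src$flags[[i]], node$exclude_flags))) next
      if (length(node$attr_any)) {
        attrs <- src$attrs[[i]]
        present <- vapply(node$attr_any, function(a) !is.null(attrs[[a$attr]]), FALSE)
        if (!any(present)) {
          stop(sprintf(
            "record '%s': event '%s' (%s) lacks attribute(s) %s required by predicate",
            rec$record_id, src$ids[i], src$codes[i],
            paste(vapply(node$attr_any, `[[`, "", "attr"), collapse = "/")),
            call. = FALSE)
        }
        ok <- any(vapply(seq_along(node$attr_any), function(j) {
          a <- node$attr_any[[j]]
          present[j] && apply_cmp(attrs[[a$attr]], a$cmp, a$value)
        }, FALSE))
        if (!ok) next
      }
      times <- c(times, src$times[i])
      evid <- c(evid, list(src$ids[i]))
    }
  }
  matches(times, evid)
}

exp_filter <- function(node, idx, classes) {
  sel <- vapply(idx$exp_classes, function(cl) length(intersect(cl, classes)) > 0, FALSE)
  if (!is.null(node$route)) sel <- sel & idx$exp_route %in% node$route
  if (!is.null(node$abrupt_stop)) sel <- sel & idx$exp_abrupt == node$abrupt_stop
  which(sel)
}

eval_drug <- function(node, idx) {
  sel <- exp_filter(node, idx, node$classes)
  matches(idx$exp_start[sel], as.list(idx$exp_ids[sel]))
}

eval_drug_after_event <- function(node, idx) {
  sel <- exp_filter(node, idx, node$classes)
  if (!length(sel)) return(no_matches())
  ev <- idx$ev
  esel <- which(ev$codes %in% node$event_codes)
  if (length(node$exclude_flags)) {
    esel <- esel[!vapply(esel, function(i) {
      length(intersect(ev$flags[[i]], node$exclude_flags)) > 0
    }, FALSE)]
    if (length(intersect(idx$rec$comorbidity_flags, node$exclude_flags))) {
      esel <- integer()
    }
  }
  if (!length(esel)) return(no_matches())
  times <- numeric(); evid <- list()
  for (i in sel) {
    st <- idx$exp_start[i]
    ok <- esel[ev$times[esel] <= st & st <= ev$times[esel] + node$window_h]
    if (length(ok)) {
      times <- c(times, st)
      evid <- c(evid, list(c(idx$exp_ids[i], ev$ids[ok[1]])))
    }
  }
  matches(times, evid)
}

eval_drug_after_drug <- function(node, idx) {
  sel <- exp_filter(node, idx, node$classes)
  if (!length(sel)) return(no_matches())
  prior <- which(vapply(idx$exp_classes, function(cl) {
    length(intersect(cl, node$prior_classes)) > 0
  }, FALSE))
  if (!length(prior)) return(no_matches())
  times <- numeric(); evid <- list()
  for (i in sel) {
    st <- idx$exp_start[i]
    ok <- prior[prior != i & idx$exp_start[prior] <= st &
                  st <= idx$exp_stop[prior] + node$window_h]
    if (length(ok)) {
      times <- c(times, st)
      evid <- c(evid, list(c(idx$exp_ids[i], idx$exp_ids[ok[1]])))
    }
  }
  matches(times, evid)
}

eval_aki <- function(node, idx) {
  labs <- idx$labs
  scr <- which(labs$analyte == "SCr")
  ur <- which(labs$analyte == "urine_output_rate")
  if (!length(scr) && !length(ur)) return(no_matches())
  qt <- aki_rule(
    if (length(scr)) data.frame(time = labs$time[scr], value = labs$value[scr],
                                is_baseline = labs$is_baseline[scr]) else NULL,
    if (length(ur)) data.frame(time = labs$time[ur],
                               value = labs$value[ur]) else NULL
  )
  if (!length(qt)) return(no_matches())
  rel <- c(scr, ur)
  evid <- lapply(qt, function(t) {
    near <- rel[labs$time[rel] <= t]
    if (length(near)) labs$lab_id[near[which.max(labs$time[near])]] else
      labs$lab_id[rel[1]]
  })
  matches(qt, evid)
}

eval_liver <- function(node, idx) {
  labs <- idx$labs
  alt <- which(labs$analyte == "ALT")
  alp <- which(labs$analyte == "ALP")
  if (!length(alt) || !length(alp)) return(no_matches())
  rec <- idx$rec
  times <- numeric(); evid <- list()
  for (i in alt) {
    dt <- abs(labs$time[alp] - labs$time[i])
    j <- alp[which.min(dt)]
    if (min(dt) > node$window_h) next
    res <- liver_injury_rule(labs$value[i], labs$value[j], rec$alt_uln,
                             rec$alp_uln)
    if (res$pattern != "none") {
      times <- c(times, max(labs$time[i], labs$time[j]))
      evid <- c(evid, list(c(labs$lab_id[i], labs$lab_id[j])))
    }
  }
  matches(times, evid)
}

eval_guard <- function(node, idx) {
  rec <- idx$rec
  ok <- TRUE
  if (!is.null(node$delivery_mode_not)) {
    ok <- ok && !rec$delivery_mode %in% node$delivery_mode_not
  }
  if (!is.null(node$delivery_mode_in)) {
    ok <- ok && rec$delivery_mode %in% node$delivery_mode_in
  }
  if (!is.null(node$requires_class)) {
    ok <- ok && record_has_class(idx, node$requires_class)
  }
  if (!is.null(node$requires_status)) {
    ok <- ok && identical(rec$diabetic_status, node$requires_status)
  }
  ok
}

eval_not <- function(node, idx) {
  r <- eval_node(node$children[[1]], idx)
  if (is_guard_result(r)) !r else length(r$times) == 0
}

eval_all <- function(node, idx) {
  results <- lapply(node$children, eval_node, idx = idx)
  guards <- vapply(results, is_guard_result, FALSE)
  if (any(guards) && !all(unlist(results[guards]))) return(no_matches())
  mr <- results[!guards]
  if (!length(mr)) {
    # pure guard conjunction: a single untimed record-level match
    return(matches(0, list(character())))
  }
  if (any(vapply(mr, function(m) length(m$times) == 0, FALSE))) {
    return(no_matches())
  }
  anchor <- mr[[1]]
  extra <- unlist(lapply(mr[-1], function(m) m$evidence[[1]]))
  matches(anchor$times, lapply(anchor$evidence, function(e) unique(c(e, extra))))
}

eval_any <- function(node, idx) {
  times <- numeric(); evid <- list()
  for (ch in node$children) {
    r <- eval_node(ch, idx)
    if (is_guard_result(r)) {
      stop("guard node cannot be a direct child of pred_any()", call. = FALSE)
    }
    times <- c(times, r$times)
    evid <- c(evid, r$evidence)
  }
  matches(times, evid)
}
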
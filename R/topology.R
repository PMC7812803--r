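#' cMyc+ subpopulation states
#'
#' Integer codes used internally by the simulator; exported for tests and
#' downstream tables. `NONE` is the cMyc-negative baseline.
#' @keywords internal
SUBPOPS <- c(NONE = 0L, EARLY = 1L, PREPB = 2L, LATE_INT = 3L,
             LATE_LO = 4L, DZ_CMYC = 5L)

subpop_label <- function(code) names(SUBPOPS)[match(code, SUBPOPS)]

TRIGGERS <- c("on_selection", "on_fate_output", "on_fate_recycle",
              "timer", "on_cb_differentiation", "cmyc_loss_timer", "gc_exit")

#' Construct a cMyc+ subpopulation transition topology
#'
#' A topology is a directed graph over the cMyc+ subpopulation states with
#' event- and timer-triggered edges:
#' * `on_selection` — entry edge from `NONE`, fired when a light-zone cell
#'   passes the selection threshold;
#' * `on_fate_output` / `on_fate_recycle` — a probabilistic fate-decision pair
#'   leaving one state after the dwell time named by `param` (output with
#'   probability `p_output`, recycling with `p_recycle`);
#' * `timer` — deterministic transition after the dwell named by `param`;
#' * `on_cb_differentiation` — timed transition into `DZ_CMYC`; the cell
#'   re-enters the dark zone as a centroblast;
#' * `cmyc_loss_timer` — timed loss of cMyc (transition to `NONE`);
#' * `gc_exit` — timed exit from the GC as an output cell (plasmablast or
#'   memory precursor).
#'
#' @param name Topology name.
#' @param edges Tibble with columns `from`, `to`, `trigger`, `param`
#'   (parameter name, `NA` for `on_selection`).
#' @param params Tibble with columns `name`, `hours`, `free` (logical: a fit
#'   target rather than a fixed constant).
#' @return An object of class `gc_topology`.
#' @seealso [model_zero()], [topology_alternatives()], [validate_topology()]
#' @export
gc_topology <- function(name, edges, params) {
  edges <- tibble::as_tibble(edges)
  params <- tibble::as_tibble(params)
  stopifnot(all(c("from", "to", "trigger", "param") %in% names(edges)),
            all(c("name", "hours", "free") %in% names(params)))
  topo <- structure(list(name = name, edges = edges, params = params),
                    class = "gc_topology")
  validate_topology(topo)
  topo
}

#' @export
print.gc_topology <- function(x, ...) {
  cat("<gc_topology> ", x$name, "\n", sep = "")
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %-8s -> %-8s  [%s%s]\n", e$from, e$to, e$trigger,
                ifelse(is.na(e$param), "", paste0(": ", e$param))))
  }
  p <- x$params
  cat("  parameters: ",
      paste0(p$name, " = ", p$hours, "h", ifelse(p$free, " (free)", ""),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The working subpopulation topology (model 0)
#'
#' Selection puts a cell into `EARLY`. After a dwell `t_early` the cell makes
#' the probabilistic fate decision: the output branch goes to `PREPB` (which
#' dwells `t_prepb` inside the GC and then exits as output), the recycling
#' branch to `LATE_INT`. `LATE_INT` splits into `LATE_LO` after `t_split`;
#' `LATE_LO` differentiates into a dark-zone centroblast (`DZ_CMYC`) after
#' `t_latelo`; cMyc is lost a fixed time `t_dzloss` after dark-zone entry.
#'
#' @param t_early,t_split,t_latelo,t_dzloss,t_prepb Dwell times in hours.
#' @return A `gc_topology`.
#' @export
model_zero <- function(t_early = 1, t_split = 12, t_latelo = 3,
                       t_dzloss = 5, t_prepb = 6) {
  gc_topology(
    name = "model0",
    edges = tibble::tribble(
      ~from,      ~to,        ~trigger,                ~param,
      "NONE",     "EARLY",    "on_selection",          NA_character_,
      "EARLY",    "PREPB",    "on_fate_output",        "t_early",
      "EARLY",    "LATE_INT", "on_fate_recycle",       "t_early",
      "LATE_INT", "LATE_LO",  "timer",                 "t_split",
      "LATE_LO",  "DZ_CMYC",  "on_cb_differentiation", "t_latelo",
      "DZ_CMYC",  "NONE",     "cmyc_loss_timer",       "t_dzloss",
      "PREPB",    "NONE",     "gc_exit",               "t_prepb"
    ),
    params = tibble::tibble(
      name = c("t_early", "t_split", "t_latelo", "t_dzloss", "t_prepb"),
      hours = c(t_early, t_split, t_latelo, t_dzloss, t_prepb),
      free = c(TRUE, TRUE, TRUE, TRUE, TRUE)
    )
  )
}

#' Illustrative alternative topologies
#'
#' Four alternative transition graphs used by the model-selection examples and
#' the model-recovery tests. They are illustrative constructions exploring the
#' neighborhood of the working model (prePB branching later in the chain,
#' direct dark-zone entry, no late split, fate decision at the last light-zone
#' state); they are not reconstructions of any externally specified variants.
#'
#' @return Named list of `gc_topology` objects.
#' @export
topology_alternatives <- function() {
  list(
    prepb_from_late = gc_topology(
      "prepb_from_late",
      edges = tibble::tribble(
        ~from,      ~to,        ~trigger,                ~param,
        "NONE",     "EARLY",    "on_selection",          NA_character_,
        "EARLY",    "LATE_INT", "timer",                 "t_early",
        "LATE_INT", "PREPB",    "on_fate_output",        "t_split",
        "LATE_INT", "LATE_LO",  "on_fate_recycle",       "t_split",
        "LATE_LO",  "DZ_CMYC",  "on_cb_differentiation", "t_latelo",
        "DZ_CMYC",  "NONE",     "cmyc_loss_timer",       "t_dzloss",
        "PREPB",    "NONE",     "gc_exit",               "t_prepb"
      ),
      params = tibble::tibble(
        name = c("t_early", "t_split", "t_latelo", "t_dzloss", "t_prepb"),
        hours = c(1, 12, 3, 5, 6), free = rep(TRUE, 5))
    ),
    direct_dz = gc_topology(
      "direct_dz",
      edges = tibble::tribble(
        ~from,     ~to,       ~trigger,          ~param,
        "NONE",    "EARLY",   "on_selection",    NA_character_,
        "EARLY",   "PREPB",   "on_fate_output",  "t_early",
        "EARLY",   "DZ_CMYC", "on_fate_recycle", "t_early",
        "DZ_CMYC", "NONE",    "cmyc_loss_timer", "t_dzloss",
        "PREPB",   "NONE",    "gc_exit",         "t_prepb"
      ),
      params = tibble::tibble(
        name = c("t_early", "t_dzloss", "t_prepb"),
        hours = c(1, 5, 6), free = rep(TRUE, 3))
    ),
    no_split = gc_topology(
      "no_split",
      edges = tibble::tribble(
        ~from,      ~to,        ~trigger,                ~param,
        "NONE",     "EARLY",    "on_selection",          NA_character_,
        "EARLY",    "PREPB",    "on_fate_output",        "t_early",
        "EARLY",    "LATE_INT", "on_fate_recycle",       "t_early",
        "LATE_INT", "DZ_CMYC",  "on_cb_differentiation", "t_split",
        "DZ_CMYC",  "NONE",     "cmyc_loss_timer",       "t_dzloss",
        "PREPB",    "NONE",     "gc_exit",               "t_prepb"
      ),
      params = tibble::tibble(
        name = c("t_early", "t_split", "t_dzloss", "t_prepb"),
        hours = c(1, 15, 5, 6), free = rep(TRUE, 4))
    ),
    latelo_fate = gc_topology(
      "latelo_fate",
      edges = tibble::tribble(
        ~from,      ~to,        ~trigger,          ~param,
        "NONE",     "EARLY",    "on_selection",    NA_character_,
        "EARLY",    "LATE_INT", "timer",           "t_early",
        "LATE_INT", "LATE_LO",  "timer",           "t_split",
        "LATE_LO",  "PREPB",    "on_fate_output",  "t_latelo",
        "LATE_LO",  "DZ_CMYC",  "on_fate_recycle", "t_latelo",
        "DZ_CMYC",  "NONE",     "cmyc_loss_timer", "t_dzloss",
        "PREPB",    "NONE",     "gc_exit",         "t_prepb"
      ),
      params = tibble::tibble(
        name = c("t_early", "t_split", "t_latelo", "t_dzloss", "t_prepb"),
        hours = c(1, 12, 3, 5, 6), free = rep(TRUE, 5))
    )
  )
}

#' Validate a topology
#'
#' Checks structural soundness: known states and triggers, a single
#' `on_selection` entry edge from `NONE`, fate edges in output/recycle pairs
#' sharing a dwell parameter, at most one rule (fate pair, timer, or exit) per
#' state, dwell parameters present and positive, `on_cb_differentiation`
#' targeting `DZ_CMYC`, `cmyc_loss_timer` targeting `NONE`, and acyclicity
#' over the cMyc+ states (excluding the `NONE` baseline).
#'
#' @param topology A `gc_topology`.
#' @return The topology, invisibly; errors describe the offending edge or
#'   parameter.
#' @export
validate_topology <- function(topology) {
  e <- topology$edges
  p <- topology$params
  states <- names(SUBPOPS)
  bad <- setdiff(unique(c(e$from, e$to)), states)
  if (length(bad)) stop("unknown state(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(e$trigger), TRIGGERS)
  if (length(bad)) stop("unknown trigger(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  sel <- e[e$trigger == "on_selection", ]
  if (nrow(sel) != 1L || sel$from != "NONE" || sel$to == "NONE")
    stop("exactly one on_selection edge from NONE is required", call. = FALSE)
  timed <- e[e$trigger != "on_selection", ]
  if (anyNA(timed$param))
    stop("every timed edge needs a dwell parameter", call. = FALSE)
  missing <- setdiff(timed$param, p$name)
  if (length(missing))
    stop("dwell parameter(s) not defined: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(p$hours) | p$hours <= 0))
    stop("all dwell parameters must be positive and finite", call. = FALSE)
  for (s in setdiff(unique(timed$from), "NONE")) {
    es <- timed[timed$from == s, ]
    n_fate <- sum(es$trigger %in% c("on_fate_output", "on_fate_recycle"))
    if (n_fate > 0) {
      if (n_fate != 2L || nrow(es) != 2L ||
          length(unique(es$param)) != 1L ||
          !setequal(es$trigger, c("on_fate_output", "on_fate_recycle")))
        stop("state ", s, ": fate edges must be exactly one output/recycle ",
             "pair sharing a dwell parameter", call. = FALSE)
    } else if (nrow(es) != 1L) {
      stop("state ", s, " has more than one non-fate exit edge",
           call. = FALSE)
    }
  }
  cb <- e[e$trigger == "on_cb_differentiation", ]
  if (nrow(cb) && any(cb$to != "DZ_CMYC"))
    stop("on_cb_differentiation must target DZ_CMYC", call. = FALSE)
  loss <- e[e$trigger == "cmyc_loss_timer", ]
  if (nrow(loss) && any(loss$to != "NONE"))
    stop("cmyc_loss_timer must target NONE", call. = FALSE)
  gx <- e[e$trigger == "gc_exit", ]
  if (nrow(gx) && any(gx$to != "NONE"))
    stop("gc_exit edges are written as transitions to NONE", call. = FALSE)
  # acyclicity over cMyc+ states (gc_exit and cmyc_loss leave the machine)
  live <- e[!(e$trigger %in% c("on_selection", "gc_exit", "cmyc_loss_timer")) &
              e$to != "NONE", ]
  adj <- split(live$to, live$from)
  visit <- function(s, stack) {
    if (s %in% stack)
      stop("cycle through state ", s, call. = FALSE)
    for (nxt in adj[[s]] %||% character()) visit(nxt, c(stack, s))
  }
  for (s in names(adj)) visit(s, character())
  invisible(topology)
}

# Compile a topology into integer-coded per-state rules for the hot loop.
# Returns list(sel_target, rules) where rules[[code]] is NULL or a list with
# $type in {"fate","timer","exit"}.
compile_topology <- function(topology) {
  e <- topology$edges
  p <- stats::setNames(topology$params$hours, topology$params$name)
  rules <- vector("list", 5L)
  sel_target <- SUBPOPS[[e$to[e$trigger == "on_selection"]]]
  for (s in setdiff(unique(e$from), "NONE")) {
    code <- SUBPOPS[[s]]
    es <- e[e$from == s & e$trigger != "on_selection", ]
    if (any(es$trigger == "on_fate_output")) {
      rules[[code]] <- list(
        type = "fate",
        dwell = p[[es$param[1L]]],
        out_to = SUBPOPS[[es$to[es$trigger == "on_fate_output"]]],
        rec_to = SUBPOPS[[es$to[es$trigger == "on_fate_recycle"]]]
      )
    } else if (es$trigger[1L] == "gc_exit") {
      rules[[code]] <- list(type = "exit", dwell = p[[es$param[1L]]])
    } else {
      rules[[code]] <- list(type = "timer", dwell = p[[es$param[1L]]],
                            to = SUBPOPS[[es$to[1L]]])
    }
  }
  fate_first <- order(vapply(rules, function(r)
    is.null(r) || r$type != "fate", logical(1)))
  list(sel_target = sel_target, rules = rules,
       order = fate_first[!vapply(rules[fate_first], is.null, logical(1))],
       name = topology$name)
}

#' Update topology dwell parameters
#'
#' @param topology A `gc_topology`.
#' @param point Named list or one-row data frame of parameter values (hours).
#'   Names must exist in `topology$params`.
#' @return The topology with updated parameter hours.
#' @export
set_topology_params <- function(topology, point) {
  point <- as.list(point)
  unknown <- setdiff(names(point), topology$params$name)
  if (length(unknown))
    stop("unknown topology parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  i <- match(names(point), topology$params$name)
  topology$params$hours[i] <- as.numeric(unlist(point))
  validate_topology(topology)
  topology
}

#' Write / read a topology as YAML
#'
#' @param topology A `gc_topology`.
#' @param path File path.
#' @return `write_topology` returns `path` invisibly; `read_topology` returns
#'   the validated `gc_topology`.
#' @export
write_topology <- function(topology, path) {
  obj <- list(
    name = topology$name,
    edges = purrr::pmap(topology$edges, function(from, to, trigger, param)
      list(from = from, to = to, trigger = trigger,
           param = if (is.na(param)) NULL else param)),
    params = purrr::pmap(topology$params, function(name, hours, free)
      list(name = name, hours = hours, free = free))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- yaml::read_yaml(path)
  edges <- purrr::map_dfr(obj$edges, function(e)
    tibble::tibble(from = e$from, to = e$to, trigger = e$trigger,
                   param = e$param %||% NA_character_))
  params <- purrr::map_dfr(obj$params, tibble::as_tibble)
  gc_topology(obj$name, edges, params)
}
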
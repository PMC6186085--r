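#' Simulation scenarios
#'
#' A scenario fixes the two controllable dimensions of a simulation: the p53
#' genotype (`wt` or `null`, the latter clamping the p53 node to inactive to
#' mimic loss of function) and the DNA-damage input (`ON` or `OFF`, e.g.
#' treatment with a DNA-damaging chemotherapeutic vs. untreated).
#'
#' @param p53 `"wt"` or `"null"`.
#' @param damage `"ON"` or `"OFF"`.
#' @return An object of class `lssa_scenario`.
#' @examples
#' lssa_scenario("wt", "ON")
#' @export
lssa_scenario <- function(p53 = c("wt", "null"), damage = c("ON", "OFF")) {
  p53 <- match.arg(p53)
  damage <- match.arg(damage)
  structure(list(p53 = p53, damage = damage), class = "lssa_scenario")
}

#' @export
print.lssa_scenario <- function(x, ...) {
  cat(sprintf("Scenario: TP53 %s, DNA damage %s\n", x$p53, x$damage))
  invisible(x)
}

scenario_label <- function(sc) sprintf("p53_%s_damage_%s", sc$p53, sc$damage)

# Kleene three-valued OR over a numeric vector with NaN = undetermined.
# Empty input is 0 (no regulator of that polarity contributes).
kleene_or <- function(v) {
  if (any(v == 1, na.rm = TRUE)) return(1)
  if (length(v) == 0 || all(v == 0, na.rm = TRUE) && !anyNA(v)) return(0)
  NaN
}

#' Three-valued logical steady state
#'
#' Computes the logical steady state of every node under a scenario. Each node
#' is inactive (0), active (1) or undetermined (`NaN`). The input node is
#' clamped to 1 when DNA damage is ON, 0 when OFF; under a `null` scenario the
#' p53 node is clamped to 0 (knockout as clamping, so downstream logic sees an
#' inactive node). Source nodes other than the input are uncontrolled and stay
#' `NaN`. Every other node takes the value
#' `OR(activators) AND NOT OR(inhibitors)` in Kleene three-valued logic, and
#' the state vector is the least fixpoint of this monotone update started from
#' all-undetermined, so unforced cycles resolve to `NaN`. Convergence takes at
#' most one sweep per node.
#'
#' @param net a [p53_network()] object.
#' @param scenario an [lssa_scenario()].
#' @return An object of class `lssa_state`: a named numeric vector of states
#'   in `{0, NaN, 1}` over all nodes, with the scenario attached as an
#'   attribute.
#' @examples
#' st <- lssa_steady_state(toy_p53_network(), lssa_scenario("wt", "ON"))
#' st[c("TP53", "APAF1", "E2F1")]
#' @export
lssa_steady_state <- function(net, scenario) {
  stopifnot(inherits(net, "p53net"), inherits(scenario, "lssa_scenario"))
  ids <- node_ids(net)
  n <- length(ids)
  state <- stats::setNames(rep(NaN, n), ids)

  clamped <- stats::setNames(logical(n), ids)
  state[net$input_node] <- if (scenario$damage == "ON") 1 else 0
  clamped[net$input_node] <- TRUE
  if (scenario$p53 == "null") {
    state[net$p53_node] <- 0
    clamped[net$p53_node] <- TRUE
  }

  act_in <- split(net$edges$source[net$edges$sign == 1],
                  net$edges$target[net$edges$sign == 1])
  inh_in <- split(net$edges$source[net$edges$sign == -1],
                  net$edges$target[net$edges$sign == -1])
  regulated <- ids %in% net$edges$target
  # uncontrolled sources (no regulators, not the input) remain NaN
  free <- ids[!clamped & regulated]

  for (sweep in seq_len(n + 1L)) {
    changed <- FALSE
    for (v in free) {
      a <- kleene_or(state[act_in[[v]]])
      i <- kleene_or(state[inh_in[[v]]])
      # Kleene AND(a, NOT i)
      new <- if (identical(a, 0) || identical(i, 1)) 0
             else if (identical(a, 1) && identical(i, 0)) 1
             else NaN
      old <- state[[v]]
      if (!(identical(is.nan(old), is.nan(new)) &&
            (is.nan(new) || old == new))) {
        state[[v]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(state, scenario = scenario, class = "lssa_state")
}

#' @export
print.lssa_state <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("Logical steady state (TP53 %s, DNA damage %s): %d nodes\n",
              sc$p53, sc$damage, length(x)))
  tab <- table(factor(ifelse(is.nan(unclass(x)), "NaN", unclass(x)),
                      levels = c("0", "NaN", "1")))
  cat(sprintf("  inactive: %d  undetermined: %d  active: %d\n",
              tab[["0"]], tab[["NaN"]], tab[["1"]]))
  invisible(x)
}

#' @export
as.data.frame.lssa_state <- function(x, ...) {
  data.frame(node = names(x), state = as.numeric(x), row.names = NULL)
}

#' Model-predicted change between two steady states
#'
#' Derives the per-node model prediction E_mod in \{-1, 0, +1\} (down,
#' unchanged, up) from two three-valued steady states, implementing the full
#' nine-case table over \{0, NaN, 1\} squared:
#' \tabular{lll}{
#'  S1 = 1, S2 = 0 -> -1 \tab S1 = 1, S2 = NaN -> -1 \tab S1 = NaN, S2 = 0 -> -1 \cr
#'  S1 = 1, S2 = 1 ->  0 \tab S1 = 0, S2 = 0   ->  0 \tab S1 = NaN, S2 = NaN -> 0 \cr
#'  S1 = 0, S2 = 1 -> +1 \tab S1 = NaN, S2 = 1 -> +1 \tab S1 = 0, S2 = NaN -> +1
#' }
#' Equivalently, with NaN ranked between inactive and active, E_mod is the
#' sign of the rank change; swapping the two states negates every prediction.
#'
#' @param state1,state2 [lssa_steady_state()] results (or named vectors over
#'   `{0, NaN, 1}`) for the source and target scenario, over the same nodes.
#' @return Named integer vector of E_mod values in `{-1, 0, 1}`.
#' @examples
#' derive_emod(c(A = 1, B = NaN), c(A = 0, B = 1))  # A: -1, B: +1
#' @export
derive_emod <- function(state1, state2) {
  s1 <- unclass(state1); s2 <- unclass(state2)
  if (is.null(names(s1)) || is.null(names(s2)) ||
      !setequal(names(s1), names(s2)) || length(s1) != length(s2))
    stop("states must cover the same node set")
  s2 <- s2[names(s1)]
  rank3 <- function(s) ifelse(is.nan(s), 0.5, s)  # 0 < NaN < 1
  out <- as.integer(sign(rank3(s2) - rank3(s1)))
  stats::setNames(out, names(s1))
}
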
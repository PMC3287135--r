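# Signed influence graphs and network-topology heuristics for predicting
# perturbation, evaluated against the measured spectral distance D.

#' Build the signed influence graph of a reaction network
#'
#' A species A has a positive influence on species B when A is a substrate
#' or enzyme (modifier) of a reaction that produces B: more A, more B
#' produced. A has a negative influence on B when B is net-consumed by a
#' reaction in which A is a substrate or enzyme: more A, more B consumed.
#' Production/consumption are judged on net stoichiometry, so catalysts do
#' not influence themselves through their own reactions; self-edges are
#' excluded. Parallel edges of opposite sign between the same pair are
#' kept.
#'
#' @param net a [reaction_network()].
#' @return An `influence_graph`: `nodes` (species names) and `edges`
#'   (data frame with columns `from`, `to`, `sign`).
#' @export
build_influence_graph <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  S <- stoichiometry(net)
  from <- character(); to <- character(); sign <- integer()
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    infl <- unique(c(names(r$reactants), r$modifiers))
    produced <- rownames(S)[S[, j] > 0]
    consumed <- rownames(S)[S[, j] < 0]
    for (a in infl) {
      for (b in setdiff(produced, a)) {
        from <- c(from, a); to <- c(to, b); sign <- c(sign, 1L)
      }
      for (b in setdiff(consumed, a)) {
        from <- c(from, a); to <- c(to, b); sign <- c(sign, -1L)
      }
    }
  }
  edges <- unique(data.frame(from = from, to = to, sign = sign,
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  structure(list(nodes = names(net$species), edges = edges),
            class = "influence_graph")
}

#' @export
print.influence_graph <- function(x, ...) {
  cat(sprintf("<influence_graph> %d nodes, %d signed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges[, c("from", "to")], directed = TRUE,
                                vertices = g$nodes)
}

#' Minimum network distance from a source species
#'
#' Directed shortest-path length in steps, ignoring edge signs. Species
#' with no directed path from the source are unreachable and reported as
#' `Inf`.
#'
#' @param g an [build_influence_graph()] result.
#' @param source source species name.
#' @return Named numeric vector of distances (0 for the source itself,
#'   `Inf` if unreachable).
#' @export
min_distance <- function(g, source) {
  stopifnot(inherits(g, "influence_graph"))
  if (!source %in% g$nodes) stop("unknown source species: ", source)
  d <- igraph::distances(as_igraph(g), v = source, mode = "out")[1, ]
  d[g$nodes]
}

# enumerate all simple directed paths from source up to max_len, summing
# 1/length and sign/length per target (depth-first; graphs here are small)
path_proximity <- function(g, source, max_len) {
  stopifnot(inherits(g, "influence_graph"))
  if (!source %in% g$nodes) stop("unknown source species: ", source)
  stopifnot(max_len >= 1)
  adj <- split(g$edges[, c("to", "sign")], g$edges$from)
  w <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  sw <- w
  visited <- stats::setNames(logical(length(g$nodes)), g$nodes)
  recurse <- function(node, len, sgn) {
    out <- adj[[node]]
    if (is.null(out)) return(invisible())
    for (i in seq_len(nrow(out))) {
      nb <- out$to[i]
      if (visited[[nb]]) next
      s2 <- sgn * out$sign[i]
      w[[nb]] <<- w[[nb]] + 1 / (len + 1)
      sw[[nb]] <<- sw[[nb]] + s2 / (len + 1)
      if (len + 1 < max_len) {
        visited[[nb]] <<- TRUE
        recurse(nb, len + 1, s2)
        visited[[nb]] <<- FALSE
      }
    }
  }
  visited[[source]] <- TRUE
  recurse(source, 0L, 1L)
  list(weighted = w, signed = sw)
}

#' Weighted all-paths proximity
#'
#' Sum over all simple directed paths from the source to each species of
#' the inverse path length, combining the effects of all routes of
#' influence with shorter paths weighted more heavily. Signs are ignored.
#'
#' @inheritParams min_distance
#' @param max_len maximum path length considered; defaults to the number of
#'   nodes (so every simple path is included).
#' @return Named numeric vector of proximities (0 for unreachable species).
#' @export
weighted_proximity <- function(g, source, max_len = length(g$nodes)) {
  path_proximity(g, source, max_len)$weighted
}

#' Signed all-paths proximity
#'
#' As [weighted_proximity()], but each path contributes `sign / length`
#' where the path sign is the product of its edge signs, so antagonistic
#' routes cancel.
#'
#' @inheritParams weighted_proximity
#' @return Named numeric vector.
#' @export
signed_proximity <- function(g, source, max_len = length(g$nodes)) {
  path_proximity(g, source, max_len)$signed
}

#' Evaluate a topology heuristic against measured perturbation
#'
#' Ordinary least-squares fit (with intercept) of the measured per-species
#' distance D on the heuristic score; the coefficient of determination R2
#' summarises how well topology predicts the measured perturbation (1:
#' perfect, 0: no predictive ability). Species with non-finite scores
#' (unreachable) are excluded by default since no principled finite
#' distance exists for them.
#'
#' @param scores named numeric vector of heuristic scores.
#' @param measured_D named numeric vector of measured distances D.
#' @param include_unreachable if `TRUE`, non-finite scores are replaced by
#'   0 and retained.
#' @return A `heuristic_evaluation`: `r_squared`, `slope`, `intercept`,
#'   `species`, `n`.
#' @export
evaluate_heuristic <- function(scores, measured_D,
                               include_unreachable = FALSE) {
  common <- intersect(names(scores), names(measured_D))
  s <- scores[common]
  d <- measured_D[common]
  if (include_unreachable) s[!is.finite(s)] <- 0
  keep <- is.finite(s) & is.finite(d)
  s <- s[keep]; d <- d[keep]
  if (length(s) < 3)
    stop("need at least 3 species with finite score and D (have ",
         length(s), ")")
  if (stats::var(s) == 0 || stats::var(d) == 0) {
    # no score variance (nothing to predict with) or no response variance
    # (nothing to explain): zero predictive ability by convention
    fit <- list(slope = 0, intercept = mean(d), r2 = 0)
  } else {
    m <- stats::lm(d ~ s)
    fit <- list(slope = unname(stats::coef(m)[2]),
                intercept = unname(stats::coef(m)[1]),
                r2 = suppressWarnings(summary(m)$r.squared))
  }
  structure(list(r_squared = fit$r2, slope = fit$slope,
                 intercept = fit$intercept, species = names(s),
                 n = length(s)),
            class = "heuristic_evaluation")
}

#' @export
print.heuristic_evaluation <- function(x, ...) {
  cat(sprintf("<heuristic_evaluation> R^2 = %.3f over %d species\n",
              x$r_squared, x$n))
  invisible(x)
}

#' Export an influence graph
#'
#' `write_influence_graph()` writes the signed edge list as CSV
#' (`from,to,sign`) or as GraphML.
#'
#' @param g an influence graph.
#' @param path output path.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_influence_graph <- function(g, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(g$edges, path, row.names = FALSE)
  } else {
    ig <- as_igraph(g)
    igraph::E(ig)$sign <- g$edges$sign
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}
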
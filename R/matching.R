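#' Goodness of fit between a component map and a template mask
#'
#' The template-matching score: mean absolute amplitude inside the mask
#' minus mean absolute amplitude outside it. Absolute amplitudes make the
#' score invariant to the arbitrary sign of an independent component.
#'
#' @param component_map Numeric array (z-like amplitudes).
#' @param template Logical (or 0/1) array of the same dimensions; must
#'   contain at least one voxel inside and one outside.
#' @return A single unitless score; higher is better.
#' @export
goodness_of_fit <- function(component_map, template) {
  template <- as.logical(template)
  if (length(component_map) != length(template)) {
    abort("component map and template must share one grid",
          class = "fnconn_invalid_argument")
  }
  n_in <- sum(template)
  if (n_in == 0L || n_in == length(template)) {
    abort("template mask must be non-empty and not cover the whole grid",
          class = "fnconn_invalid_argument")
  }
  a <- abs(as.numeric(component_map))
  mean(a[template]) - mean(a[!template])
}

# Hungarian algorithm (shortest augmenting path, potentials) minimising
# total cost over injective row -> column assignments of an n x m cost
# matrix with n <= m.  Column index m + 1 plays the role of the virtual
# start column; way[j] remembers the previous column on the alternating
# path.  Returns the assigned column index per row.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) abort("assignment needs at least as many columns as rows",
                   class = "fnconn_infeasible_matching")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n)
  v <- numeric(m + 1)
  p_col <- integer(m + 1)   # row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p_col[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(INF, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p_col[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p_col[j] > 0L) u[p_col[j]] <- u[p_col[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p_col[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p_col[j0] <- p_col[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p_col[j] > 0L) assignment[p_col[j]] <- j
  assignment
}

#' Match RSN templates to independent components
#'
#' Solves the constrained matching problem of RSN identification: every
#' template must be assigned to exactly one component and no component may
#' be claimed twice. The injective assignment maximising the total
#' [goodness_of_fit()] over the 10 x n score matrix is found by the
#' Hungarian algorithm; ties are broken deterministically by template name
#' order (rows are processed in template order).
#'
#' @param components A [spatial_component_set()] with at least as many
#'   components as templates.
#' @param templates A [rsn_templates()] set.
#' @return A list of class `match_result`: `mapping` (named character,
#'   template -> component id), `gof` (score per match), `unmatched`
#'   (component ids claimed by no template), and `scores` (the full
#'   template x component score matrix).
#' @export
match_templates <- function(components, templates) {
  if (!inherits(components, "spatial_component_set")) {
    abort("`components` must be a spatial_component_set",
          class = "fnconn_invalid_argument")
  }
  if (!inherits(templates, "template_set")) {
    abort("`templates` must be a template_set",
          class = "fnconn_invalid_argument")
  }
  if (!identical(as.integer(components$dim), as.integer(templates$dim))) {
    abort("components and templates must share one grid",
          class = "fnconn_invalid_argument")
  }
  n_t <- length(templates$masks)
  n_c <- length(components$maps)
  if (n_c < n_t) {
    abort(sprintf("need at least %d components, got %d", n_t, n_c),
          class = "fnconn_infeasible_matching")
  }
  scores <- matrix(NA_real_, n_t, n_c,
                   dimnames = list(names(templates$masks),
                                   names(components$maps)))
  for (t in seq_len(n_t)) {
    for (c in seq_len(n_c)) {
      scores[t, c] <- goodness_of_fit(components$maps[[c]],
                                      templates$masks[[t]])
    }
  }
  assignment <- solve_assignment(-scores)  # maximise total score
  mapping <- setNames(colnames(scores)[assignment], rownames(scores))
  structure(
    list(mapping = mapping,
         gof = setNames(scores[cbind(seq_len(n_t), assignment)],
                        rownames(scores)),
         unmatched = setdiff(colnames(scores), mapping),
         scores = scores),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d templates matched, %d components unclaimed\n",
              length(x$mapping), length(x$unmatched)))
  invisible(x)
}

#' @describeIn match_templates One row per template
#'   (`template`, `component`, `gof`).
#' @param x A `match_result`.
#' @param ... Unused.
#' @export
tidy.match_result <- function(x, ...) {
  tibble::tibble(template = names(x$mapping),
                 component = unname(x$mapping),
                 gof = unname(x$gof))
}
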
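#' Specification of a synthetic multi-group cohort
#'
#' Describes the three study populations (healthy controls and two patient
#' groups with increasingly severe disorders of consciousness) as graded
#' degradations of a common base coupling graph. For group `g`, each edge of
#' the base graph is independently deleted with probability
#' `edge_deletion_prob`, surviving weights are multiplied by
#' `1 - weight_attenuation`, and node noise is scaled by `noise_inflation`.
#'
#' @param n_subjects Named integer vector of group sizes. The default
#'   `c(HC = 27, MCS = 24, UWS = 24)` mirrors the cohort sizes of the
#'   target study design.
#' @param n_timepoints Samples per subject (default 297).
#' @param sampling_interval Repetition time in seconds (default 2).
#' @param base_graph A [coupling_graph()]; defaults to a density-0.4 graph
#'   over the 10 canonical RSNs.
#' @param degradation Named list, one entry per group, each a list with
#'   `edge_deletion_prob` in `[0, 1]`, `weight_attenuation` in `[0, 1]` and
#'   `noise_inflation >= 1`.
#' @param noise_sd Baseline per-node noise standard deviation.
#' @param seed Integer master seed; subject-level seeds are derived
#'   deterministically from it.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects = c(HC = 27, MCS = 24, UWS = 24),
                        n_timepoints = 297, sampling_interval = 2,
                        base_graph = NULL,
                        degradation = default_degradation(names(n_subjects)),
                        noise_sd = 0.5, seed = 1) {
  if (is.null(names(n_subjects)) || anyDuplicated(names(n_subjects))) {
    abort("`n_subjects` must be a named vector with unique group labels",
          class = "fnconn_invalid_argument")
  }
  stopifnot_scalar_count(n_timepoints, "n_timepoints", min = 32L)
  if (is.null(base_graph)) {
    base_graph <- generate_coupling_graph(10, density = 0.4, seed = seed)
  }
  if (!setequal(names(degradation), names(n_subjects))) {
    abort("`degradation` must have one entry per group",
          class = "fnconn_invalid_argument")
  }
  for (g in names(degradation)) {
    d <- degradation[[g]]
    if (d$edge_deletion_prob < 0 || d$edge_deletion_prob > 1 ||
        d$weight_attenuation < 0 || d$weight_attenuation > 1 ||
        d$noise_inflation < 1) {
      abort(sprintf("invalid degradation parameters for group %s", g),
            class = "fnconn_invalid_argument")
    }
  }
  structure(
    list(n_subjects = n_subjects, n_timepoints = as.integer(n_timepoints),
         sampling_interval = sampling_interval, base_graph = base_graph,
         degradation = degradation, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default per-group degradation parameters
#'
#' Healthy controls keep the base graph intact; the minimally conscious
#' group loses a quarter of the edges and a quarter of the surviving
#' coupling strength; the unresponsive group loses half of each, with
#' proportionally inflated noise. These graded values encode the working
#' assumption that disorders of consciousness weaken between-network
#' coupling monotonically with severity.
#'
#' @param groups Group labels (default the HC/MCS/UWS triple).
#' @return Named list of degradation parameter lists.
#' @export
default_degradation <- function(groups = c("HC", "MCS", "UWS")) {
  levels <- list(
    HC  = list(edge_deletion_prob = 0,    weight_attenuation = 0,    noise_inflation = 1),
    MCS = list(edge_deletion_prob = 0.25, weight_attenuation = 0.25, noise_inflation = 1.25),
    UWS = list(edge_deletion_prob = 0.5,  weight_attenuation = 0.5,  noise_inflation = 1.5)
  )
  out <- levels[intersect(groups, names(levels))]
  for (g in setdiff(groups, names(levels))) {
    out[[g]] <- levels$HC
  }
  out[groups]
}

# Apply group degradation to the base graph using the supplied seed.
degrade_graph <- function(graph, deg, seed) {
  withr::with_seed(seed, {
    W <- graph$weights
    L <- graph$lags
    NL <- graph$nonlinearity
    ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    if (nrow(ut) > 0 && deg$edge_deletion_prob > 0) {
      drop <- runif(nrow(ut)) < deg$edge_deletion_prob
      for (k in which(drop)) {
        W[ut[k, 1], ut[k, 2]] <- W[ut[k, 2], ut[k, 1]] <- 0
        L[ut[k, 1], ut[k, 2]] <- L[ut[k, 2], ut[k, 1]] <- 0L
      }
    }
    W <- W * (1 - deg$weight_attenuation)
    coupling_graph(W, L, NL, labels = graph$labels)
  })
}

#' Generate a synthetic cohort
#'
#' Draws every subject of every group from the degraded version of the base
#' coupling graph (see [cohort_spec()]). Each subject receives an
#' independently degraded graph realisation (edge deletion is resampled per
#' subject) and a deterministic seed derived from the master seed, the group
#' index and the subject index, so any subject can be regenerated in
#' isolation.
#'
#' @param spec A [cohort_spec()].
#' @return Named list (one element per group) of lists of
#'   [timecourse_set()] objects.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = c(HC = 3, MCS = 2, UWS = 2), seed = 7)
#' cohort <- generate_cohort(spec)
#' names(cohort)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec", class = "fnconn_invalid_argument")
  }
  groups <- names(spec$n_subjects)
  out <- setNames(vector("list", length(groups)), groups)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    deg <- spec$degradation[[g]]
    subs <- vector("list", spec$n_subjects[[g]])
    for (si in seq_len(spec$n_subjects[[g]])) {
      s_graph <- derive_seed(spec$seed, gi, si, 1L)
      s_tc <- derive_seed(spec$seed, gi, si, 2L)
      graph_s <- degrade_graph(spec$base_graph, deg, s_graph)
      subs[[si]] <- simulate_timecourses(
        graph_s,
        n_timepoints = spec$n_timepoints,
        sampling_interval = spec$sampling_interval,
        noise_sd = spec$noise_sd * deg$noise_inflation,
        seed = s_tc,
        group = g,
        subject = sprintf("%s-%02d", g, si)
      )
    }
    out[[g]] <- subs
  }
  out
}
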
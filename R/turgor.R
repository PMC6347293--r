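# Turgor estimation from incipient-plasmolysis assays.

#' Limit-plasmolysis osmolarity from plasmolysis fraction tables
#'
#' The limit (incipient) plasmolysis concentration `c_pl` is the external
#' osmolarity at which half of the apical cells are plasmolyzed. Each
#' experiment's response is fitted with a binomial logistic model in
#' `log(c_e)` and `c_pl` taken where the fitted probability crosses 0.5;
#' alternatively the two observations straddling 0.5 are linearly
#' interpolated.
#'
#' @param tab Data frame with columns `experiment_id`, `c_e` (mOsm/L),
#'   `n_total`, `n_plasmolyzed`.
#' @param method `"logistic"` (default) or `"interpolation"`.
#' @return List with `c_pl` (mean over experiments, mOsm/L) and
#'   `per_experiment` (named vector of per-experiment values).
#' @export
limit_plasmolysis <- function(tab, method = c("logistic", "interpolation")) {
  method <- match.arg(method)
  need <- c("experiment_id", "c_e", "n_total", "n_plasmolyzed")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$c_e <= 0)) stop("osmolarities must be positive")
  if (any(tab$n_plasmolyzed < 0 | tab$n_plasmolyzed > tab$n_total))
    stop("plasmolyzed counts outside [0, n_total]")
  ids <- unique(tab$experiment_id)
  per <- vapply(ids, function(id) {
    d <- tab[tab$experiment_id == id, , drop = FALSE]
    d <- d[order(d$c_e), , drop = FALSE]
    frac <- d$n_plasmolyzed / d$n_total
    if (max(frac) < 0.5 || min(frac) > 0.5)
      stop("experiment '", id, "': plasmolysis fractions never cross 50%")
    if (method == "logistic") {
      fit <- stats::glm(cbind(n_plasmolyzed, n_total - n_plasmolyzed) ~
                          log(c_e), family = stats::binomial(), data = d)
      b <- stats::coef(fit)
      exp(-b[[1L]] / b[[2L]])
    } else {
      i <- which(frac >= 0.5)[1L]
      if (i == 1L) return(d$c_e[1L])
      f1 <- frac[i - 1L]; f2 <- frac[i]
      d$c_e[i - 1L] + (0.5 - f1) / (f2 - f1) * (d$c_e[i] - d$c_e[i - 1L])
    }
  }, numeric(1))
  names(per) <- as.character(ids)
  list(c_pl = mean(per), per_experiment = per)
}

#' Turgor from limit plasmolysis with shrink correction
#'
#' Plasmolyzed cells have shrunk, so the internal osmolarity under normal
#' growth is `c_i = shrink * c_pl` with `shrink` the plasmolyzed-to-normal
#' volume ratio. Turgor is `P = (c_i - c_sea) / 410` MPa, `c_sea` being the
#' seawater osmolarity.
#'
#' @param c_pl Limit-plasmolysis osmolarity, mOsm/L.
#' @param shrink Volume ratio V(plasmolyzed)/V(normal), in (0, 1].
#' @param c_sea External (seawater) osmolarity, mOsm/L.
#' @return Turgor pressure P, MPa.
#' @export
turgor_from_plasmolysis <- function(c_pl, shrink = 1, c_sea = 1100) {
  if (shrink <= 0 || shrink > 1) stop("shrink ratio must be in (0, 1]")
  (shrink * c_pl - c_sea) / 410
}

#' Cell volume shrink coefficient upon plasmolysis
#'
#' @param volume_pairs Data frame or matrix with columns `V_plasmo`,
#'   `V_normal` (one row per cell), or a list of such pairs.
#' @return Mean of per-cell ratios V_plasmo / V_normal.
#' @export
shrink_coefficient <- function(volume_pairs) {
  vp <- as.data.frame(volume_pairs)
  if (nrow(vp) == 0L) stop("no volume pairs supplied")
  if (any(vp[[1L]] <= 0) || any(vp[[2L]] <= 0))
    stop("volumes must be positive")
  mean(vp[[1L]] / vp[[2L]])
}
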
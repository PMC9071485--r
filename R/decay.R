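## mRNA decay kinetics from transcription-shutoff (actinomycin-D) time
## courses. After transcription stops, remaining mRNA follows first-order
## kinetics dC/dt = -k*C, so ln(C/C0) = -k*t and the half-life is
## t1/2 = ln(2)/k. k is estimated as the through-origin least-squares slope
## of -ln(C/C0) against time.

#' Normalise a decay time course to its 0 h value
#'
#' Divides every abundance by the value at t = 0 so the series starts at 1,
#' the convention for actinomycin-D chase experiments.
#'
#' @param raw positive abundance values, one per time point.
#' @param timepoints time points in hours; the first must be 0 and the
#'   vector strictly increasing.
#' @return data.frame with columns \code{timepoint_h} and
#'   \code{rel_abundance} (first value exactly 1).
#' @examples
#' normalizeDecaySeries(c(4, 2, 1), c(0, 2, 4))
#' @export
normalizeDecaySeries <- function(raw, timepoints) {
  stopifnot(length(raw) == length(timepoints), length(raw) >= 1L)
  if (timepoints[1L] != 0) stop("the series must include t = 0 first")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (!is.finite(raw[1L]) || raw[1L] <= 0)
    stop("the t = 0 abundance must be positive")
  data.frame(timepoint_h = timepoints, rel_abundance = raw / raw[1L])
}

#' Fit first-order decay to one gene's time course
#'
#' Regresses \code{-ln(C/C0)} on time. By default the line is constrained
#' through the origin, matching the model \code{ln(C/C0) = -k*t} which has
#' no intercept; a free-intercept fit is available for diagnostics. The
#' coefficient of determination is reported relative to the fitted model
#' (for the through-origin fit, \code{1 - RSS/sum(y^2)}). A non-positive
#' slope (a stabilised transcript) is returned with \code{t_half = Inf},
#' not treated as an error.
#'
#' @param timepoints hours, first must be 0, at least 2 points.
#' @param values positive relative abundances; normalised internally so
#'   the t = 0 value is 1.
#' @param geneId optional gene identifier carried into the result.
#' @param throughOrigin constrain the intercept to 0 (default \code{TRUE}).
#' @return a \code{\linkS4class{DecayFit}}.
#' @examples
#' fit <- fitDecay(c(0, 2, 4), c(1, 0.5, 0.25))
#' kDecay(fit)      # ln(2)/2
#' halfLifeOf(fit)  # 2 h
#' @export
fitDecay <- function(timepoints, values, geneId = NA_character_,
                     throughOrigin = TRUE) {
  stopifnot(length(timepoints) == length(values))
  if (length(timepoints) < 2L) stop("need at least 2 time points")
  if (any(!is.finite(values) | values <= 0))
    stop("all abundances must be positive and finite")
  ser <- normalizeDecaySeries(values, timepoints)
  y <- -log(ser$rel_abundance)
  t <- ser$timepoint_h
  if (throughOrigin) {
    fit <- lm(y ~ 0 + t)
    k <- unname(coef(fit)[["t"]])
    b <- 0
    ss_tot <- sum(y^2)  # through-origin convention
  } else {
    fit <- lm(y ~ t)
    k <- unname(coef(fit)[["t"]])
    b <- unname(coef(fit)[[1L]])
    ss_tot <- sum((y - mean(y))^2)
  }
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  new("DecayFit", gene_id = geneId, k_decay = k, t_half = halfLife(k),
      r_squared = r2, n_points = length(t), intercept = b)
}

#' Half-life from a first-order decay rate
#'
#' \code{t1/2 = ln(2) / k} for \code{k > 0}; \code{Inf} for \code{k <= 0}
#' (no measurable decay within the chase).
#'
#' @param kDecay decay rate constant(s), per hour.
#' @return half-life in hours, vectorised; \code{Inf} where
#'   \code{kDecay <= 0}.
#' @examples
#' halfLife(log(2))  # 1
#' halfLife(0.1)     # 6.93
#' @export
halfLife <- function(kDecay) {
  ifelse(kDecay > 0, log(2) / kDecay, Inf)
}

#' Fit decay kinetics for every gene in a long-format table
#'
#' Convenience wrapper over \code{\link{fitDecay}}. Replicates are averaged
#' per time point before fitting (one line per gene over replicate means);
#' set \code{perReplicate = TRUE} to fit each replicate separately instead.
#'
#' @param series data.frame with columns \code{gene}, \code{timepoint_h},
#'   \code{value} and optionally \code{replicate}.
#' @param throughOrigin passed to \code{\link{fitDecay}}.
#' @param perReplicate fit each replicate separately.
#' @return data.frame with one row per gene (or gene x replicate):
#'   \code{gene}, \code{k_decay}, \code{t_half}, \code{r_squared},
#'   \code{n_points}.
#' @export
fitDecayTable <- function(series, throughOrigin = TRUE,
                          perReplicate = FALSE) {
  stopifnot(all(c("gene", "timepoint_h", "value") %in% names(series)))
  if (perReplicate && "replicate" %in% names(series)) {
    key <- interaction(series$gene, series$replicate, drop = TRUE)
  } else {
    agg <- aggregate(value ~ gene + timepoint_h, data = series, FUN = mean)
    series <- agg
    key <- factor(series$gene)
  }
  parts <- split(series, key)
  rows <- lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    p <- p[order(p$timepoint_h), , drop = FALSE]
    f <- fitDecay(p$timepoint_h, p$value, geneId = as.character(p$gene[1L]),
                  throughOrigin = throughOrigin)
    data.frame(gene = f@gene_id, fit_key = nm, k_decay = f@k_decay,
               t_half = f@t_half, r_squared = f@r_squared,
               n_points = f@n_points)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative quantification by the 2^-ddCt method
#'
#' Computes \code{2^-((sample.target - sample.reference) -
#' (control.target - control.reference))}: the fold change of a qPCR
#' target in a sample relative to a control sample, each normalised to an
#' internal-control gene (e.g. Gapdh).
#'
#' @param sampleTargetCt,sampleReferenceCt Ct values for the sample.
#' @param controlTargetCt,controlReferenceCt Ct values for the control.
#' @return the fold change (vectorised over samples).
#' @examples
#' ddctFoldChange(20, 15, 22, 15)  # 4
#' @export
ddctFoldChange <- function(sampleTargetCt, sampleReferenceCt,
                           controlTargetCt, controlReferenceCt) {
  cts <- c(sampleTargetCt, sampleReferenceCt,
           controlTargetCt, controlReferenceCt)
  if (any(!is.finite(cts) | cts <= 0))
    stop("Ct values must be finite and positive")
  dSample <- sampleTargetCt - sampleReferenceCt
  dControl <- controlTargetCt - controlReferenceCt
  2^(-(dSample - dControl))
}
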
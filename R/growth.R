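# Longitudinal growth-isotropy analysis and cross-modality volume
# concordance.
#
# Growth isotropy: the equatorial volume and the projected area of the
# same islet at two sessions are each interpolated to the radius of a
# model sphere, giving two one-dimensional growth factors,
# (V2/V1)^(1/3) and (A2/A1)^(1/2). Their ratio is 1 when growth is
# direction-independent; the constant relating half- and full-sphere
# volume cancels in the ratio.

#' One-dimensional growth factors of an islet between two timepoints
#'
#' @param isletId islet label.
#' @param veq1,veq2 equatorial volumes (um^3) at the two sessions, > 0.
#' @param area1,area2 projected areas (um^2) at the two sessions, > 0.
#' @param timepoints character(2) session labels.
#' @return A one-row data.frame: \code{islet_id}, \code{t1}, \code{t2},
#'   \code{veq_t1_um3}, \code{veq_t2_um3}, \code{area_t1_um2},
#'   \code{area_t2_um2}, \code{growth_1d_from_volume},
#'   \code{growth_1d_from_area}, \code{isotropy_ratio}
#'   (= volume-derived factor / area-derived factor).
#' @examples
#' growthFactors(1, 1000, 8000, 500, 2000)  # factors 2 and 2, ratio 1
#' @export
growthFactors <- function(isletId, veq1, veq2, area1, area2,
                          timepoints = c("t1", "t2")) {
    vals <- c(veq1, veq2, area1, area2)
    if (any(!is.finite(vals)) || any(vals <= 0))
        stop("volumes and areas must be positive at both timepoints")
    gv <- (veq2 / veq1)^(1 / 3)
    ga <- (area2 / area1)^(1 / 2)
    data.frame(islet_id = isletId,
               t1 = timepoints[1], t2 = timepoints[2],
               veq_t1_um3 = veq1, veq_t2_um3 = veq2,
               area_t1_um2 = area1, area_t2_um2 = area2,
               growth_1d_from_volume = gv,
               growth_1d_from_area = ga,
               isotropy_ratio = gv / ga,
               stringsAsFactors = FALSE)
}

#' Cohort summary of growth isotropy
#'
#' Arithmetic mean and standard error of the per-islet isotropy ratio. A
#' cohort mean near 1 indicates direction-independent growth; values
#' below 1 indicate preferential lateral (xy) growth, above 1
#' preferential axial growth.
#'
#' @param records data.frame of [growthFactors()] rows (>= 2).
#' @return A list: \code{mean}, \code{sem}, \code{n}, \code{ratios}.
#' @export
cohortIsotropy <- function(records) {
    if (!is.data.frame(records) || !"isotropy_ratio" %in% names(records))
        stop("records must contain an isotropy_ratio column")
    r <- records$isotropy_ratio
    if (length(r) < 2L)
        stop("need >= 2 growth records, got ", length(r))
    list(mean = mean(r), sem = stats::sd(r) / sqrt(length(r)),
         n = length(r), ratios = r)
}

#' Cross-modality volume concordance
#'
#' Compares per-islet volumes measured by two imaging modalities (e.g.
#' in vivo backscatter confocal vs ex vivo optical projection
#' tomography). Because ex vivo processing rescales absolute volumes,
#' two complementary summaries are computed: a least-squares linear fit
#' and Pearson correlation of modality-B on modality-A volumes, and a
#' ratio-consistency statistic, the mean over all unordered islet pairs
#' (i, j) of \eqn{| \log[(V_i^A/V_j^A) / (V_i^B/V_j^B)] |}, which is
#' zero iff the two volume sets are exactly proportional and is
#' invariant to independent global rescaling of either modality.
#'
#' @param tableA,tableB volume tables (see [readVolumeTable()]) from the
#'   two modalities; islets matched on \code{(sample_id, islet_id)},
#'   requiring >= 3 matches.
#' @return A list: \code{n_islets}, \code{slope}, \code{intercept},
#'   \code{pearson_r}, \code{ratio_consistency}, \code{pairs} (data.frame
#'   of per-pair absolute log-ratio discrepancies), \code{matched}
#'   (per-islet volumes side by side).
#' @export
volumeConcordance <- function(tableA, tableB) {
    validateVolumeTable(tableA)
    validateVolumeTable(tableB)
    m <- merge(tableA[, c("sample_id", "islet_id", "volume_um3")],
               tableB[, c("sample_id", "islet_id", "volume_um3")],
               by = c("sample_id", "islet_id"),
               suffixes = c("_a", "_b"))
    if (nrow(m) < nrow(tableA) || nrow(m) < nrow(tableB))
        stop("unmatched islet ids between the two modalities")
    n <- nrow(m)
    if (n < 3L)
        stop("need >= 3 matched islets for concordance, got ", n)
    fit <- stats::lm(volume_um3_b ~ volume_um3_a, data = m)
    la <- log(m$volume_um3_a)
    lb <- log(m$volume_um3_b)
    ij <- utils::combn(n, 2L)
    disc <- abs((la[ij[1, ]] - la[ij[2, ]]) - (lb[ij[1, ]] - lb[ij[2, ]]))
    list(n_islets = n,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = stats::cor(m$volume_um3_a, m$volume_um3_b),
         ratio_consistency = mean(disc),
         pairs = data.frame(i = m$islet_id[ij[1, ]],
                            j = m$islet_id[ij[2, ]],
                            abs_log_ratio_discrepancy = disc),
         matched = m)
}
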
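#' Estimate qPCR amplification efficiency from a standard curve
#'
#' Fits Ct against log10(dilution factor) by ordinary least squares over
#' a serial-dilution series of one primer pair. The efficiency is
#' \eqn{E = 10^{-1/slope}}; perfect doubling chemistry gives a slope of
#' -3.3219 and E = 2. A warning is emitted when E falls outside the
#' usual [1.8, 2.1] working range.
#'
#' @param dilution dilution factors (> 0), at least 3 distinct values
#' @param ct observed Ct per dilution (replicates allowed)
#' @param primer_pair label carried through to the result
#' @return object of class \code{efficiency_fit}: primer_pair,
#'   efficiency, slope, intercept, r2, n_points
#' @export
estimate_efficiency <- function(dilution, ct, primer_pair = NA_character_) {
  stopifnot(length(dilution) == length(ct))
  if (any(dilution <= 0)) stop("dilution factors must be > 0")
  if (length(unique(dilution)) < 3L)
    stop("standard curve needs >= 3 distinct dilution factors")
  x <- log10(dilution)
  fit <- lm(ct ~ x)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("standard-curve slope must be negative (got ", signif(slope, 4), ")")
  E <- 10^(-1 / slope)
  if (E < 1.8 || E > 2.1)
    warning("efficiency ", signif(E, 4), " outside [1.8, 2.1] for ",
            primer_pair)
  r2 <- summary(fit)$r.squared
  structure(list(primer_pair = primer_pair, efficiency = E,
                 slope = slope, intercept = unname(coef(fit)[1L]),
                 r2 = r2, n_points = length(ct)),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("<efficiency_fit> %s: E = %.4f (slope %.4f, r2 %.4f, n %d)\n",
              x$primer_pair, x$efficiency, x$slope, x$r2, x$n_points))
  invisible(x)
}

#' Efficiency-corrected relative levels by delta-delta-Ct
#'
#' Implements the comparative Ct model: replicate Cts are averaged
#' arithmetically per timepoint, then for each timepoint t
#' \deqn{\Delta\Delta Ct(t) = (Ct_{t,target} - Ct_{t,ref}) -
#'       (Ct_{0,target} - Ct_{0,ref})}
#' and the relative level is \eqn{E^{-\Delta\Delta Ct}}. At t = 0 the
#' fold is 1 by construction. When replicate indices align between
#' target and reference, per-replicate folds are also returned for
#' spread estimation.
#'
#' @param target_cts data.frame \code{timepoint, replicate, ct} for the
#'   target primer pair
#' @param reference_cts same layout for the reference pair (e.g. the
#'   ACT1 exon2 amplicon); must cover every target timepoint
#' @param E amplification efficiency (default 2 = perfect doubling)
#' @return data.table \code{timepoint, ddct, fold, fold_sd, n_rep}
#' @export
relative_level <- function(target_cts, reference_cts, E = 2) {
  tg <- data.table::as.data.table(target_cts)
  rf <- data.table::as.data.table(reference_cts)
  for (d in list(tg, rf))
    if (!all(c("timepoint", "replicate", "ct") %in% names(d)))
      stop("Ct input needs columns timepoint, replicate, ct")
  tps <- sort(unique(tg$timepoint))
  if (!0 %in% tps) stop("target Cts must include timepoint 0")
  missing_ref <- setdiff(tps, unique(rf$timepoint))
  if (length(missing_ref))
    stop("reference Cts missing at timepoint(s): ",
         paste(missing_ref, collapse = ", "))
  tavg <- tg[, .(ct = mean(ct)), by = timepoint]
  ravg <- rf[, .(ct = mean(ct)), by = timepoint]
  dct0 <- tavg[timepoint == 0, ct] - ravg[timepoint == 0, ct]
  out <- lapply(tps, function(tp) {
    ddct <- (tavg[timepoint == tp, ct] - ravg[timepoint == tp, ct]) - dct0
    # per-replicate ddct via paired replicate indices (spread only)
    pair <- merge(tg[timepoint == tp, .(replicate, ct)],
                  rf[timepoint == tp, .(replicate, rct = ct)],
                  by = "replicate")
    pair0 <- merge(tg[timepoint == 0, .(replicate, ct)],
                   rf[timepoint == 0, .(replicate, rct = ct)],
                   by = "replicate")
    folds <- if (nrow(pair) >= 2L && nrow(pair0) == nrow(pair)) {
      E^-((pair$ct - pair$rct) - (pair0$ct - pair0$rct))
    } else numeric()
    data.table(timepoint = tp, ddct = ddct, fold = E^-ddct,
               fold_sd = if (length(folds) >= 2L) sd(folds) else NA_real_,
               n_rep = nrow(tg[timepoint == tp]))
  })
  data.table::rbindlist(out)
}

#' qPCR PM index from intron and exon relative levels
#'
#' \eqn{PMi_{qPCR} = \log_2(fold_{intron} / fold_{exon})} at a common
#' timepoint (15 min by default). The spread combines the relative
#' spreads of the two folds in quadrature, on the log2 scale.
#'
#' @param intron_level,exon_level outputs of \code{\link{relative_level}}
#' @param timepoint timepoint (minutes) at which to take the index
#' @return list \code{pmi, sd, timepoint}
#' @export
compute_pmi_qpcr <- function(intron_level, exon_level, timepoint = 15) {
  tp <- timepoint
  gi <- as.data.frame(intron_level)
  gi <- gi[gi$timepoint == tp, ]
  ge <- as.data.frame(exon_level)
  ge <- ge[ge$timepoint == tp, ]
  if (nrow(gi) != 1L || nrow(ge) != 1L)
    stop("both levels must contain timepoint ", timepoint)
  if (gi$fold <= 0 || ge$fold <= 0)
    stop("internal error: non-positive fold")
  sd_log2 <- function(f, s) if (is.na(s)) NA_real_ else (s / f) / log(2)
  s2 <- c(sd_log2(gi$fold, gi$fold_sd), sd_log2(ge$fold, ge$fold_sd))
  list(pmi = log2(gi$fold / ge$fold),
       sd = if (anyNA(s2)) NA_real_ else sqrt(sum(s2^2)),
       timepoint = timepoint)
}

#' Full qPCR analysis of a Ct table
#'
#' Convenience driver: estimates per-primer efficiencies from the
#' standard-curve block (falling back to E = 2 with a warning for pairs
#' without a curve), computes relative levels for every
#' \code{<gene>_intron} / \code{<gene>_exon} pair against the reference
#' pair, and the per-gene qPCR PMi at the requested timepoint.
#'
#' @param ct_table from \code{\link{read_ct_table}}
#' @param reference reference primer-pair name (default "ACT1_exon2")
#' @param timepoint PMi timepoint (minutes)
#' @param estimate_e estimate efficiencies from dilution rows (TRUE) or
#'   assume E = 2 for all pairs (FALSE)
#' @return list: \code{pmi} (data.table gene, pmi_qpcr, sd),
#'   \code{levels} (per pair and timepoint), \code{efficiencies}
#' @export
qpcr_pmi_table <- function(ct_table, reference = "ACT1_exon2",
                           timepoint = 15, estimate_e = TRUE) {
  dt <- data.table::as.data.table(ct_table)
  std <- dt[!is.na(dilution)]
  obs <- dt[is.na(dilution)]
  if (!reference %in% obs$primer_pair)
    stop("reference primer pair '", reference, "' not found")
  pairs <- setdiff(unique(obs$primer_pair), reference)
  effs <- lapply(setNames(nm = unique(obs$primer_pair)), function(pp) {
    s <- std[primer_pair == pp]
    if (estimate_e && nrow(s) >= 3L)
      estimate_efficiency(s$dilution, s$ct, pp)
    else {
      if (estimate_e)
        warning("no standard curve for ", pp, "; assuming E = 2")
      structure(list(primer_pair = pp, efficiency = 2, slope = NA_real_,
                     intercept = NA_real_, r2 = NA_real_, n_points = 0L),
                class = "efficiency_fit")
    }
  })
  ref_cts <- obs[primer_pair == reference,
                 .(timepoint, replicate, ct)]
  levels <- lapply(setNames(nm = pairs), function(pp) {
    relative_level(obs[primer_pair == pp, .(timepoint, replicate, ct)],
                   ref_cts, E = effs[[pp]]$efficiency)
  })
  genes <- unique(sub("_(intron|exon)$", "",
                      grep("_(intron|exon)$", pairs, value = TRUE)))
  pmi <- data.table::rbindlist(lapply(genes, function(g) {
    ip <- paste0(g, "_intron"); ep <- paste0(g, "_exon")
    if (!ip %in% pairs || !ep %in% pairs)
      return(data.table(gene = g, pmi_qpcr = NA_real_, sd = NA_real_))
    r <- compute_pmi_qpcr(levels[[ip]], levels[[ep]], timepoint)
    data.table(gene = g, pmi_qpcr = r$pmi, sd = r$sd)
  }))
  list(pmi = pmi, levels = levels, efficiencies = effs)
}
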
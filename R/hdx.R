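#' Reference parameters for intrinsic amide exchange
#'
#' Loads the bundled poly-DL-alanine-based reference set for amide hydrogen
#' exchange into D2O: per-residue nearest-neighbour log10 factors for acid-
#' and base-catalysed exchange, the reference rate constants at 293 K, the
#' D2O ion product and the Arrhenius activation energies used for
#' temperature correction.
#'
#' @return List with `factors` (data frame keyed by one-letter residue code,
#'   plus `NT`/`CT` rows for the chain termini), `log_ka`, `log_kb`,
#'   `log_kw` (log10 of min^-1-based rate constants), `pkd`, `t_ref` (K) and
#'   activation energies `ea` (kcal/mol, named acid/base/water).
#' @export
hdx_reference_table <- function() {
  path <- system.file("extdata", "hdx_reference_rates.csv", package = "uchfold",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  rownames(tab) <- tab$residue
  list(
    factors = tab,
    log_ka = 1.62, log_kb = 10.05, log_kw = -1.5,
    pkd = 15.05, t_ref = 293,
    ea = c(acid = 14, base = 17, water = 19)
  )
}

#' Intrinsic (random-coil) amide exchange rate
#'
#' Additive log-factor model: the exchange rate of the backbone amide of
#' residue `i` is
#' `k_int = kA 10^(AL_i + AR_{i-1}) [D+] + (kB [OD-] + kW) 10^(BL_i + BR_{i-1})`
#' where `AL`/`BL` are the acid/base factors of residue i's own side chain,
#' `AR`/`BR` those of the preceding side chain, with additional terms for a
#' free N-terminal amine (residue 2) and the C-terminal carboxylate (last
#' residue). `[D+] = 10^-pD`, `[OD-] = 10^(pD - pKD)`. Each catalytic term is
#' Arrhenius-corrected from the 293 K reference using its activation energy.
#'
#' @param sequence One-letter amino-acid string (or character vector).
#' @param residue_index 1-based position(s); must be >= 2 (the N-terminal
#'   residue has no observable backbone amide in this model) and not proline.
#' @param pd Corrected pD of the exchange buffer.
#' @param temperature Sample temperature, K.
#' @param reference Parameter set from [hdx_reference_table()].
#' @return Intrinsic exchange rate(s), s^-1.
#' @examples
#' intrinsic_exchange_rate("MAHHHLAG", 4, pd = 8.0, temperature = 298)
#' @export
intrinsic_exchange_rate <- function(sequence, residue_index, pd = 8.0,
                                    temperature = 298,
                                    reference = hdx_reference_table()) {
  seq_vec <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  seq_vec <- toupper(seq_vec)
  n <- length(seq_vec)
  fac <- reference$factors
  known <- setdiff(rownames(fac), c("NT", "CT"))
  if (!all(seq_vec %in% known)) {
    stop("unknown residue code(s): ",
         paste(unique(seq_vec[!seq_vec %in% known]), collapse = ", "))
  }
  if (pd < 0 || pd > 14) stop("pD must be in [0, 14]")

  vapply(residue_index, function(i) {
    if (i < 2L || i > n) {
      stop(sprintf("residue_index %d out of range (2..%d): residue 1 has no observable amide", i, n))
    }
    if (seq_vec[i] == "P") {
      stop(sprintf("residue %d is proline: no exchangeable backbone amide proton", i))
    }
    al <- fac[seq_vec[i], "acid_l"] + fac[seq_vec[i - 1L], "acid_r"]
    bl <- fac[seq_vec[i], "base_l"] + fac[seq_vec[i - 1L], "base_r"]
    if (i == 2L) {
      al <- al + fac["NT", "acid_r"]
      bl <- bl + fac["NT", "base_r"]
    }
    if (i == n) {
      al <- al + fac["CT", "acid_l"]
      bl <- bl + fac["CT", "base_l"]
    }
    r_kcal <- 1.9872e-3
    arrh <- function(ea) exp(-(ea / r_kcal) * (1 / temperature - 1 / reference$t_ref))
    d_conc <- 10^(-pd)
    od_conc <- 10^(pd - reference$pkd)
    k_min <- 10^(reference$log_ka + al) * d_conc * arrh(reference$ea[["acid"]]) +
      10^(reference$log_kb + bl) * od_conc * arrh(reference$ea[["base"]]) +
      10^(reference$log_kw + bl) * arrh(reference$ea[["water"]])
    k_min / 60  # min^-1 -> s^-1
  }, numeric(1L))
}

#' Single-exponential fit of an HDX intensity decay
#'
#' Cross-peak intensity versus exchange time is fitted to
#' `I(t) = I0 exp(-k t)` (optionally plus a free floor). A series whose
#' total fractional decay is below `detection_fraction` is reported as below
#' the detection bound rather than given a rate.
#'
#' @param times Exchange times, s, strictly increasing.
#' @param intensities Peak intensities (>= 0).
#' @param free_floor If `TRUE` a constant floor is fitted; default fixes the
#'   floor at 0 (a fully exchanged peak vanishes).
#' @param detection_fraction Minimum fractional intensity loss required to
#'   call a decay.
#' @return List with `k_obs` (s^-1, `NA` when below detection), `se`, `i0`,
#'   `floor`, `status` (`"ok"` or `"below_detection"`), and for
#'   below-detection series `k_upper_bound`.
#' @export
fit_exchange_decay <- function(times, intensities, free_floor = FALSE,
                               detection_fraction = 0.05) {
  stopifnot(length(times) == length(intensities), length(times) >= 4L,
            all(diff(times) > 0), all(times >= 0), all(intensities >= 0))
  i0_guess <- max(intensities)
  drop_frac <- 1 - min(intensities) / max(i0_guess, 1e-300)
  if (drop_frac < detection_fraction) {
    return(list(k_obs = NA_real_, se = NA_real_, i0 = mean(intensities),
                floor = 0, status = "below_detection",
                k_upper_bound = -log(1 - detection_fraction) / max(times)))
  }
  k0 <- {
    half <- intensities <= i0_guess / 2
    if (any(half)) log(2) / times[which(half)[1L]] else 1 / max(times)
  }
  resid <- if (free_floor) {
    function(p) intensities - (p[1L] * exp(-exp(p[2L]) * times) + p[3L])
  } else {
    function(p) intensities - p[1L] * exp(-exp(p[2L]) * times)
  }
  p0 <- if (free_floor) c(i0_guess, log(k0), min(intensities)) else c(i0_guess, log(k0))
  fit <- minpack.lm::nls.lm(p0, fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 300,
                                                                 ftol = 1e-15))
  k_hat <- exp(fit$par[2L])
  dof <- length(times) - length(p0)
  cov <- try(solve(fit$hessian) * sum(fit$fvec^2) / max(dof, 1L),
             silent = TRUE)
  se <- if (inherits(cov, "try-error")) NA_real_ else k_hat * sqrt(cov[2L, 2L])
  list(k_obs = k_hat, se = se, i0 = fit$par[1L],
       floor = if (free_floor) fit$par[3L] else 0, status = "ok")
}

#' Protection factor of a backbone amide
#'
#' `PF = k_int / k_obs`: how much slower the amide exchanges in the folded
#' protein than the random-coil (intrinsic) prediction.
#'
#' @param k_int Intrinsic exchange rate, s^-1 (> 0).
#' @param k_obs_hdx Observed exchange rate, s^-1 (> 0), or `NA` for a
#'   below-detection decay with `k_upper_bound` supplied.
#' @param residue_index Optional residue position stored in the record.
#' @param k_upper_bound Upper bound on k_obs for below-detection series; the
#'   returned PF is then a lower bound (`bound = TRUE`).
#' @return List with `residue_index`, `k_obs_hdx`, `k_int`, `pf`,
#'   `log10_pf`, `bound`, `anomalous` (`TRUE` when pf < 1).
#' @examples
#' protection_factor(1, 1e-8)$log10_pf # 8
#' @export
protection_factor <- function(k_int, k_obs_hdx, residue_index = NA_integer_,
                              k_upper_bound = NA_real_) {
  stopifnot(k_int > 0)
  bound <- FALSE
  if (is.na(k_obs_hdx)) {
    if (is.na(k_upper_bound)) stop("need k_obs_hdx or k_upper_bound")
    k_obs_hdx <- k_upper_bound
    bound <- TRUE
  }
  stopifnot(k_obs_hdx > 0)
  pf <- k_int / k_obs_hdx
  list(residue_index = residue_index, k_obs_hdx = k_obs_hdx, k_int = k_int,
       pf = pf, log10_pf = log10(pf), bound = bound, anomalous = pf < 1)
}

#' Per-residue protection factors from HDX decay series
#'
#' Runs the full per-residue pipeline: exponential decay fit of each
#' intensity series, intrinsic rate from the sequence, PF = k_int/k_obs.
#' Residues whose decays are below detection are reported as PF lower
#' bounds; residues with too few points are skipped with a message.
#'
#' @param series_list Named list (names = residue indices) of lists with
#'   `times` and `intensities`, or a long data frame with columns
#'   `residue`, `time`, `intensity`.
#' @param sequence One-letter amino-acid sequence of the construct.
#' @param pd,temperature Exchange conditions (see
#'   [intrinsic_exchange_rate()]).
#' @return Data frame with columns `residue`, `k_obs`, `k_int`, `pf`,
#'   `log10_pf`, `bound`.
#' @export
hdx_protection_factors <- function(series_list, sequence, pd = 8.0,
                                   temperature = 298) {
  if (is.data.frame(series_list)) {
    stopifnot(all(c("residue", "time", "intensity") %in% names(series_list)))
    series_list <- lapply(split(series_list, series_list$residue), function(d) {
      d <- d[order(d$time), ]
      list(times = d$time, intensities = d$intensity)
    })
  }
  ref <- hdx_reference_table()
  rows <- lapply(names(series_list), function(nm) {
    i <- as.integer(nm)
    s <- series_list[[nm]]
    if (length(s$times) < 4L) {
      message(sprintf("residue %d skipped: fewer than 4 time points", i))
      return(NULL)
    }
    dec <- fit_exchange_decay(s$times, s$intensities)
    ki <- intrinsic_exchange_rate(sequence, i, pd = pd,
                                  temperature = temperature, reference = ref)
    rec <- protection_factor(ki, dec$k_obs, residue_index = i,
                             k_upper_bound = dec$k_upper_bound)
    data.frame(residue = i, k_obs = rec$k_obs_hdx, k_int = ki,
               pf = rec$pf, log10_pf = rec$log10_pf, bound = rec$bound)
  })
  out <- do.call(rbind, rows)
  out[order(out$residue), , drop = FALSE]
}

#' Compare protection-factor profiles across proteins
#'
#' Summarises per-residue log10 PF tables by secondary-structure segment and
#' ranks the proteins by overall median protection.
#'
#' @param profiles Named list of PF tables (as from
#'   [hdx_protection_factors()], needing columns `residue`, `log10_pf`).
#' @param segments Data frame with columns `segment`, `start`, `end`
#'   (residue ranges; must be non-empty).
#' @return List with `segment_medians` (segment x protein matrix of median
#'   log10 PF) and `ordering` (protein names, most protected first).
#' @export
compare_pf_profiles <- function(profiles, segments) {
  stopifnot(length(profiles) >= 2L, is.data.frame(segments),
            all(c("segment", "start", "end") %in% names(segments)))
  if (nrow(segments) == 0L) stop("empty segment annotation")
  med <- sapply(profiles, function(p) {
    vapply(seq_len(nrow(segments)), function(i) {
      in_seg <- p$residue >= segments$start[i] & p$residue <= segments$end[i]
      if (!any(in_seg)) return(NA_real_)
      stats::median(p$log10_pf[in_seg])
    }, 1)
  })
  rownames(med) <- segments$segment
  if (all(is.na(med))) stop("no residues fall in any annotated segment")
  overall <- apply(med, 2L, stats::median, na.rm = TRUE)
  list(segment_medians = med,
       ordering = names(sort(overall, decreasing = TRUE)))
}
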
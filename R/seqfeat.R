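# Sequence-composition features for phase-separation scoring.
#
# All features operate on uppercase amino-acid strings over the canonical
# 20-letter alphabet plus X. X is excluded from composition counts but still
# contributes length to denominators, so ambiguous residues dilute rather
# than inflate every proportion.

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

charge_of <- function(chars) {
  ifelse(chars %in% c("K", "R"), 1L, ifelse(chars %in% c("D", "E"), -1L, 0L))
}

#' Mean normalized Kyte-Doolittle hydropathy
#'
#' Each residue's Kyte-Doolittle value is rescaled to `[0, 1]` via
#' `(KD + 4.5) / 9` and averaged over the sequence. `X` residues are excluded
#' from the mean.
#'
#' @param seq Amino-acid string (canonical 20 letters plus `X`).
#' @return A fraction in `[0, 1]`.
#' @examples
#' mean_hydropathy("IIII") # 1: isoleucine is the most hydrophobic residue
#' mean_hydropathy("RRRR") # 0
#' @export
mean_hydropathy <- function(seq) {
  chars <- check_sequence(seq)
  chars <- chars[chars != "X"]
  if (length(chars) == 0) {
    abort_ps("hydropathy undefined: sequence contains only X residues",
             "psdosage_feature_error")
  }
  mean((KD_SCALE[chars] + 4.5) / 9)
}

#' Net charge per residue
#'
#' `(count(K, R) - count(D, E)) / length`, with histidine treated as neutral
#' (the convention at neutral pH). `X` counts toward the denominator only.
#'
#' @inheritParams mean_hydropathy
#' @return A value in `[-1, 1]`.
#' @export
ncpr <- function(seq) {
  chars <- check_sequence(seq)
  sum(charge_of(chars)) / length(chars)
}

# --- kappa charge patterning -------------------------------------------------

# sigma = (f+ - f-)^2 / (f+ + f-), the charge-asymmetry statistic.
# delta_g = mean over sliding windows of size g of (sigma_window - sigma)^2;
# delta = average of delta_5 and delta_6 (the Das-Pappu blob sizes).
kappa_delta <- function(charges) {
  L <- length(charges)
  fp <- sum(charges == 1L) / L
  fm <- sum(charges == -1L) / L
  sg <- if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
  tot <- 0
  for (g in c(5L, 6L)) {
    n <- L - g + 1L
    cp <- cumsum(charges == 1L)
    cm <- cumsum(charges == -1L)
    wp <- cp[seq(g, L)] - c(0, cp)[seq_len(n)]
    wm <- cm[seq(g, L)] - c(0, cm)[seq_len(n)]
    den <- wp + wm
    sw <- ifelse(den == 0, 0, (wp - wm)^2 / (g * den))
    tot <- tot + mean((sw - sg)^2)
  }
  tot / 2
}

multinomial_count <- function(np, nm, n0) {
  round(exp(lgamma(np + nm + n0 + 1) - lgamma(np + 1) - lgamma(nm + 1) -
              lgamma(n0 + 1)))
}

# Exhaustive delta_max over all distinct arrangements of the charge multiset.
# Only used when the arrangement count is small (covers every sequence of
# length <= 11); boundary effects of the short sliding windows make simple
# segregated templates sub-optimal there.
kappa_dmax_exact <- function(np, nm, n0) {
  best <- -Inf
  rec <- function(prefix, a, b, cc) {
    if (a + b + cc == 0L) {
      d <- kappa_delta(prefix)
      if (d > best) best <<- d
      return(invisible())
    }
    if (a > 0L) rec(c(prefix, 1L), a - 1L, b, cc)
    if (b > 0L) rec(c(prefix, -1L), a, b - 1L, cc)
    if (cc > 0L) rec(c(prefix, 0L), a, b, cc - 1L)
  }
  rec(integer(0), np, nm, n0)
  best
}

# delta_max for long sequences: the maximizer places the two charge blocks
# contiguously with neutral padding before, between and after them
# (0^a +^np 0^b -^nm 0^c). Search over (a, b); a multiresolution grid with
# local refinement is used when the neutral count is large.
kappa_dmax_blocks <- function(np, nm, n0) {
  eval_ab <- function(a, b) {
    kappa_delta(c(rep(0L, a), rep(1L, np), rep(0L, b), rep(-1L, nm),
                  rep(0L, n0 - a - b)))
  }
  if ((n0 + 1) * (n0 + 2) / 2 <= 2500) {
    best <- -Inf
    for (a in 0:n0) for (b in 0:(n0 - a)) {
      d <- eval_ab(a, b)
      if (d > best) best <- d
    }
    return(best)
  }
  stride <- ceiling((n0 + 1) / 40)
  grid <- unique(c(seq(0L, n0, by = stride), n0))
  best <- -Inf
  best_ab <- c(0L, 0L)
  for (a in grid) for (b in grid[grid <= n0 - a]) {
    d <- eval_ab(a, b)
    if (d > best) {
      best <- d
      best_ab <- c(a, b)
    }
  }
  for (a in max(0L, best_ab[1] - stride):min(n0, best_ab[1] + stride)) {
    bs <- max(0L, best_ab[2] - stride):min(n0 - a, best_ab[2] + stride)
    for (b in bs) {
      d <- eval_ab(a, b)
      if (d > best) best <- d
    }
  }
  best
}

.kappa_cache <- new.env(parent = emptyenv())

kappa_dmax <- function(np, nm, n0) {
  key <- paste(np, nm, n0, sep = "_")
  hit <- .kappa_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (multinomial_count(np, nm, n0) <= 20000) {
    kappa_dmax_exact(np, nm, n0)
  } else {
    kappa_dmax_blocks(np, nm, n0)
  }
  .kappa_cache[[key]] <- val
  val
}

#' Das-Pappu kappa charge-patterning parameter
#'
#' Charges are assigned as D,E = -1 and K,R = +1 (histidine neutral). The
#' charge-asymmetry deviation `delta` is averaged over sliding windows of
#' size 5 and 6 and normalized by `delta_max`, the largest `delta` attainable
#' by rearranging the same residue composition, so that 0 means well-mixed
#' charges and 1 means maximal segregation.
#'
#' `delta_max` is found by exhaustive enumeration of charge arrangements when
#' the composition admits few of them (all sequences up to length 11), and by
#' searching neutral-padded segregated block arrangements otherwise.
#'
#' @inheritParams mean_hydropathy
#' @return A fraction in `[0, 1]`, or `-1` when kappa is undefined (sequence
#'   shorter than 6 residues, no charged residues, or a composition with a
#'   single possible arrangement).
#' @export
kappa <- function(seq) {
  chars <- check_sequence(seq)
  if (length(chars) < 6) return(-1)
  charges <- charge_of(chars)
  np <- sum(charges == 1L)
  nm <- sum(charges == -1L)
  if (np + nm == 0L) return(-1)
  dmax <- kappa_dmax(np, nm, length(charges) - np - nm)
  if (dmax <= 0) return(-1)
  min(1, kappa_delta(charges) / dmax)
}

# --- SEG-style low-complexity detection --------------------------------------

seg_window_entropy <- function(chars, window) {
  L <- length(chars)
  n <- L - window + 1L
  idx <- match(chars, AA_CANONICAL) # X -> NA, excluded from counts
  counts <- matrix(0L, nrow = 20, ncol = n)
  # sliding composition via incremental update
  tab <- integer(20)
  for (j in seq_len(window)) if (!is.na(idx[j])) tab[idx[j]] <- tab[idx[j]] + 1L
  counts[, 1] <- tab
  if (n > 1) {
    for (i in 2:n) {
      out <- idx[i - 1L]
      inn <- idx[i + window - 1L]
      if (!is.na(out)) tab[out] <- tab[out] - 1L
      if (!is.na(inn)) tab[inn] <- tab[inn] + 1L
      counts[, i] <- tab
    }
  }
  p <- counts / window
  colSums(ifelse(p > 0, -p * log2(p), 0))
}

#' SEG-style low-complexity regions
#'
#' Sliding windows of `window` residues are scored by Shannon entropy
#' `K2 = -sum((n_i / W) * log2(n_i / W))` over the canonical alphabet.
#' Windows with `K2 <= locut` trigger a low-complexity segment; each maximal
#' run of trigger windows is extended outward over adjacent windows with
#' `K2 <= hicut`. The reported regions are the merged residue spans of all
#' qualifying windows. Only this trigger/extension stage is implemented; the
#' final minimal-probability refinement of the original SEG algorithm is
#' omitted because downstream code consumes low-complexity content only as a
#' coverage proportion.
#'
#' @inheritParams mean_hydropathy
#' @param window Sliding-window width in residues (SEG default 12).
#' @param locut Trigger entropy threshold in bits (SEG default 2.2).
#' @param hicut Extension entropy threshold in bits (SEG default 2.5).
#' @return A list with `regions`, a tibble of 1-based closed intervals
#'   (`start`, `end`), and `lcd_prop`, the fraction of residues covered.
#' @examples
#' seg_lcd(strrep("A", 30))$lcd_prop # 1: zero entropy everywhere
#' @export
seg_lcd <- function(seq, window = 12, locut = 2.2, hicut = 2.5) {
  chars <- check_sequence(seq)
  L <- length(chars)
  empty <- tibble::tibble(start = integer(0), end = integer(0))
  if (L < window) {
    return(list(regions = empty, lcd_prop = 0))
  }
  k2 <- seg_window_entropy(chars, window)
  n <- length(k2)
  trigger <- k2 <= locut
  extend <- k2 <= hicut
  if (!any(trigger)) {
    return(list(regions = empty, lcd_prop = 0))
  }
  qualifying <- logical(n)
  r <- rle(trigger)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    lo <- starts[i]
    hi <- ends[i]
    while (lo > 1L && extend[lo - 1L]) lo <- lo - 1L
    while (hi < n && extend[hi + 1L]) hi <- hi + 1L
    qualifying[lo:hi] <- TRUE
  }
  covered <- logical(L)
  for (i in which(qualifying)) covered[i:(i + window - 1L)] <- TRUE
  cr <- rle(covered)
  ce <- cumsum(cr$lengths)
  cs <- ce - cr$lengths + 1L
  regions <- tibble::tibble(start = cs[cr$values], end = ce[cr$values])
  list(regions = regions, lcd_prop = sum(covered) / L)
}

# --- disorder ----------------------------------------------------------------

parse_disorder_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  labs <- vapply(strsplit(trimws(lines), "\\s+"), function(f) f[[length(f)]], "")
  if (!all(labs %in% c("D", "O"))) {
    abort_ps("disorder file: labels must be 'D' (disordered) or 'O' (ordered)",
             "psdosage_validation_error")
  }
  labs == "D"
}

#' Per-residue disorder mask and disordered proportion
#'
#' Two modes are available. The built-in `"baseline"` mode applies the
#' Uversky charge-hydropathy boundary locally: a residue is called disordered
#' when, within its centered 25-residue window (truncated at the termini),
#' `|NCPR| > 2.785 * mean_hydropathy - 1.151`. This is an explicit baseline
#' stand-in, not a re-implementation of any trained disorder predictor, and
#' results carry `mode = "baseline"` so the two are never conflated.
#' `"external"` mode ingests a per-residue prediction file (one residue per
#' line, final column `D`/`O`), e.g. output of an ESpritz-style predictor run
#' at a 5% false-positive-rate threshold.
#'
#' @inheritParams mean_hydropathy
#' @param mode `"baseline"` or `"external"`.
#' @param path Per-residue label file, required for `"external"` mode.
#' @param window Window width for the baseline boundary.
#' @return A list with `mask` (logical, one element per residue), `idr_prop`
#'   (disordered fraction), and `mode`.
#' @export
disorder_mask <- function(seq, mode = c("baseline", "external"), path = NULL,
                          window = 25) {
  mode <- match.arg(mode)
  chars <- check_sequence(seq)
  L <- length(chars)
  if (mode == "external") {
    if (is.null(path)) {
      abort_ps("external disorder mode requires `path`",
               "psdosage_validation_error")
    }
    mask <- parse_disorder_file(path)
    if (length(mask) != L) {
      abort_ps(sprintf(
        "disorder file has %d labels but the sequence has %d residues",
        length(mask), L), "psdosage_validation_error")
    }
    return(list(mask = mask, idr_prop = mean(mask), mode = "external"))
  }
  half <- (window - 1) %/% 2
  charges <- charge_of(chars)
  hyd <- ifelse(chars == "X", NA_real_, (KD_SCALE[chars] + 4.5) / 9)
  mask <- vapply(seq_len(L), function(i) {
    j <- max(1L, i - half):min(L, i + half)
    w_ncpr <- abs(sum(charges[j])) / length(j)
    h <- hyd[j]
    h_mean <- if (all(is.na(h))) 0.5 else mean(h, na.rm = TRUE)
    w_ncpr > 2.785 * h_mean - 1.151
  }, logical(1))
  list(mask = mask, idr_prop = mean(mask), mode = "baseline")
}

#' All scalar sequence features for one region
#'
#' Convenience wrapper returning the five composition features consumed by
#' the truncation classifier as a one-row tibble, plus `kappa_defined`
#' (kappa's `-1` sentinel is passed through literally alongside this
#' indicator so tree models can split on definedness instead of relying on
#' silent imputation).
#'
#' @inheritParams disorder_mask
#' @param disorder_path Optional external per-residue disorder file; when
#'   `NULL` the baseline boundary is used.
#' @return One-row tibble with columns `hydropathy`, `kappa`, `kappa_defined`,
#'   `ncpr`, `idr_prop`, `lcd_prop`.
#' @export
sequence_features <- function(seq, disorder_path = NULL) {
  k <- kappa(seq)
  dis <- if (is.null(disorder_path)) {
    disorder_mask(seq, "baseline")
  } else {
    disorder_mask(seq, "external", disorder_path)
  }
  tibble::tibble(
    hydropathy = mean_hydropathy(seq),
    kappa = k,
    kappa_defined = as.numeric(k >= 0),
    ncpr = ncpr(seq),
    idr_prop = dis$idr_prop,
    lcd_prop = seg_lcd(seq)$lcd_prop
  )
}
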
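#' Select the analysis window for a region
#'
#' With no user window, the default is a 70 bp window starting at the first
#' CpG site (clipped to the region end). A user window `c(start, end)` is
#' 0-based half-open and is clipped to the region. The window's CpG sites
#' are those with both bases of the dinucleotide inside the window.
#'
#' @param regions Region tibble from [load_references()].
#' @param region Region name (default: first region).
#' @param window Optional numeric `c(start, end)`, 0-based half-open.
#' @param size Default window size in bases (70).
#' @return A `meth_window`: list with `region_name`, `start`, `end` (0-based
#'   half-open), `sites` (0-based CpG C offsets inside the window) and
#'   `site_index` (1-based positions of those sites among the region's CpG
#'   sites, for indexing per-read status strings).
#' @export
select_window <- function(regions, region = regions$name[1L], window = NULL, size = 70L) {
  r <- region_row(regions, region)
  if (is.null(window)) {
    if (length(r$cpg_sites) == 0L) {
      abort_mc("region '%s' has no CpG sites and no window was given", region)
    }
    start <- r$cpg_sites[1L]
    end <- min(start + size, r$length)
  } else {
    stopifnot(length(window) == 2L)
    start <- max(0L, as.integer(window[1L]))
    end <- min(as.integer(window[2L]), r$length)
    if (start >= end) abort_mc("empty window [%d, %d) for region '%s'", start, end, region)
  }
  keep <- r$cpg_sites >= start & (r$cpg_sites + 1L) < end
  if (!any(keep)) {
    abort_mc("window [%d, %d) of region '%s' contains no complete CpG site",
             start, end, region)
  }
  structure(
    list(region_name = region, start = as.integer(start), end = as.integer(end),
         sites = r$cpg_sites[keep], site_index = which(keep)),
    class = "meth_window"
  )
}

#' @export
print.meth_window <- function(x, ...) {
  cat(sprintf("<meth_window> %s [%d, %d) with %d CpG site(s): %s\n",
              x$region_name, x$start, x$end, length(x$sites),
              paste(x$sites, collapse = ", ")))
  invisible(x)
}

# internal: signature strings (over window sites) for each read; "" rows are
# reads that do not fully cover the window or carry an ambiguous call
window_signatures <- function(calls, window) {
  in_region <- calls$region_name == window$region_name
  sig <- rep("", nrow(calls))
  if (any(in_region)) {
    chars <- lapply(window$site_index, function(i) substring(calls$status[in_region], i, i))
    m <- do.call(cbind, chars)
    ok <- rowSums(m == "M" | m == "U") == ncol(m)
    sig[in_region][ok] <- apply(m[ok, , drop = FALSE], 1L, paste, collapse = "")
  }
  sig
}

#' Reads that fully cover a window
#'
#' Keeps exactly the reads that cover every CpG site in the window with a
#' definite (non-ambiguous) methylation call; only these enter co-occurrence
#' pattern generation. Reads with an ambiguous base at a window CpG are
#' excluded here but still contribute to mutation pileups.
#'
#' @param calls Methylation-call tibble (after QC filtering).
#' @param window A `meth_window` from [select_window()].
#' @return The qualifying subset of `calls`, with a `signature` column (one
#'   `M`/`U` character per window site).
#' @export
reads_covering_window <- function(calls, window) {
  sig <- window_signatures(calls, window)
  out <- calls[sig != "", , drop = FALSE]
  out$signature <- sig[sig != ""]
  out
}

#' Z statistic and one-sided p-value for a pattern's frequency
#'
#' Tests whether a pattern's observed frequency exceeds the baseline
#' probability: `Z = (p_hat - p0) / sqrt(p_hat (1 - p_hat) / n)`, with the
#' standard deviation estimated from the observed frequency, and the p-value
#' the upper tail of the standard normal (alternative: frequency greater
#' than baseline). Degenerate unanimity case `p_hat = 1` (zero denominator):
#' if alternatives were possible (`p0 < 1`) the pattern is maximally
#' significant (`z = Inf`, `p = 0`); if it is the only observed pattern
#' (`p0 = 1`) it is non-significant (`z = 0`, `p = 1`).
#'
#' @param p_hat Observed pattern fraction(s), in `(0, 1]`.
#' @param p0 Baseline probability, in `(0, 1]` (one over the number of
#'   observed patterns).
#' @param n Total read count (>= 1).
#' @return Tibble with columns `z` and `p_value` (vectorised over inputs).
#' @export
pattern_zscore <- function(p_hat, p0, n) {
  if (any(n < 1)) abort_mc("n must be >= 1")
  if (any(p_hat <= 0 | p_hat > 1) || any(p0 <= 0 | p0 > 1)) {
    abort_mc("p_hat and p0 must lie in (0, 1]")
  }
  k <- pmax(length(p_hat), length(p0), length(n))
  p_hat <- rep_len(p_hat, k); p0 <- rep_len(p0, k); n <- rep_len(n, k)
  z <- ifelse(p_hat == 1,
              ifelse(p0 < 1, Inf, 0),
              (p_hat - p0) / sqrt(p_hat * (1 - p_hat) / n))
  p <- ifelse(p_hat == 1 & p0 == 1, 1, pnorm(z, lower.tail = FALSE))
  tibble(z = z, p_value = p)
}

# internal: construct a pattern_set from signature strings
new_pattern_set <- function(signatures, window) {
  n <- length(signatures)
  if (n == 0L) {
    patterns <- tibble(signature = character(), support = integer(),
                       fraction = numeric(), z = numeric(), p_value = numeric())
    return(structure(list(region_name = window$region_name, window = window,
                          n = 0L, p0 = NA_real_, patterns = patterns),
                     class = "pattern_set"))
  }
  tab <- sort(table(signatures), decreasing = TRUE)
  p0 <- 1 / length(tab)
  patterns <- tibble(
    signature = names(tab),
    support = as.integer(tab),
    fraction = as.integer(tab) / n
  )
  zp <- pattern_zscore(patterns$fraction, p0, n)
  patterns$z <- zp$z
  patterns$p_value <- zp$p_value
  structure(list(region_name = window$region_name, window = window,
                 n = n, p0 = p0, patterns = patterns),
            class = "pattern_set")
}

#' Group window-covering reads into co-occurrence patterns
#'
#' Reads sharing the same methylation signature across all window CpG sites
#' form one co-occurrence pattern whose support is the read count. Each
#' pattern is scored against the baseline probability `p0`, defined as one
#' over the number of observed patterns (reflecting dependence among nearby
#' CpG sites, rather than the naive `1/2^k`), via [pattern_zscore()].
#'
#' @param covering Output of [reads_covering_window()] (or any tibble with a
#'   `signature` column of `M`/`U` strings).
#' @param window The `meth_window` the reads cover.
#' @return A `pattern_set`: list with `region_name`, `window`, `n` (total
#'   reads), `p0`, and `patterns` (tibble of `signature`, `support`,
#'   `fraction`, `z`, `p_value`). Zero covering reads give an empty set
#'   (`n = 0`, no patterns), not an error.
#' @export
group_patterns <- function(covering, window) {
  sig <- if ("signature" %in% names(covering)) covering$signature
         else window_signatures(covering, window)
  new_pattern_set(sig[sig != ""], window)
}

#' Build a pattern set directly from signature strings
#'
#' Lower-level constructor used in simulation studies where signatures are
#' drawn directly rather than read off aligned reads.
#'
#' @param signatures Character vector of `M`/`U` signature strings.
#' @param window Optional `meth_window`; a placeholder is synthesised from
#'   the signature length if omitted.
#' @return A `pattern_set`.
#' @export
pattern_set_from_signatures <- function(signatures, window = NULL) {
  if (is.null(window)) {
    k <- if (length(signatures) > 0L) nchar(signatures[1L]) else 0L
    window <- structure(list(region_name = "sim", start = 0L, end = 2L * k,
                             sites = 2L * seq_len(k) - 2L, site_index = seq_len(k)),
                        class = "meth_window")
  }
  new_pattern_set(signatures, window)
}

#' Significant patterns of a pattern set
#'
#' Patterns with `p_value < alpha` (and, if set, `fraction >= min_fraction`),
#' in descending order of significance: by `z`, ties by support, then by
#' signature (methylated sorts before unmethylated). An optional Bonferroni
#' correction divides `alpha` by the number of observed patterns.
#'
#' @param ps A `pattern_set`.
#' @param alpha Significance threshold on the one-sided p-value (default 0.05).
#' @param min_fraction Optional minimum pattern fraction.
#' @param bonferroni Divide `alpha` by the number of observed patterns.
#' @return Tibble of significant patterns, ordered.
#' @export
significant_patterns <- function(ps, alpha = 0.05, min_fraction = NULL, bonferroni = FALSE) {
  stopifnot(inherits(ps, "pattern_set"))
  pat <- ps$patterns
  if (nrow(pat) == 0L) return(pat)
  a <- if (bonferroni) alpha / nrow(pat) else alpha
  keep <- pat$p_value < a
  if (!is.null(min_fraction)) keep <- keep & pat$fraction >= min_fraction
  pat <- pat[keep, , drop = FALSE]
  pat[order(-pat$z, -pat$support, pat$signature), , drop = FALSE]
}

#' Chi-square test of co-methylation dependence for one CpG site pair
#'
#' Aggregates pattern supports into a 2x2 contingency table (methylated vs
#' unmethylated at site a, crossed with site b) and computes the Pearson
#' chi-square statistic with 1 degree of freedom, without continuity
#' correction. A zero margin (a site uniformly methylated or unmethylated)
#' carries no dependence information: the statistic is defined as 0 with
#' p-value 1.
#'
#' @param ps A `pattern_set`.
#' @param site_a,site_b Window site indices (1-based positions among the
#'   window's CpG sites).
#' @return List with `chi2`, `p_value`, and `table` (the 2x2 count matrix,
#'   rows = site a `M`/`U`, columns = site b `M`/`U`).
#' @export
cpg_pair_dependency <- function(ps, site_a, site_b) {
  stopifnot(inherits(ps, "pattern_set"))
  k <- length(ps$window$sites)
  if (site_a < 1L || site_a > k || site_b < 1L || site_b > k || site_a == site_b) {
    abort_mc("invalid site indices (%s, %s) for a window with %d CpG sites",
             site_a, site_b, k)
  }
  a <- substring(ps$patterns$signature, site_a, site_a)
  b <- substring(ps$patterns$signature, site_b, site_b)
  tab <- matrix(0, 2L, 2L, dimnames = list(a = c("M", "U"), b = c("M", "U")))
  for (i in seq_along(a)) {
    tab[a[i], b[i]] <- tab[a[i], b[i]] + ps$patterns$support[i]
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = 0, p_value = 1, table = tab))
  }
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - e)^2 / e)
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1L, lower.tail = FALSE), table = tab)
}

#' Chi-square dependence for all CpG site pairs in a window
#'
#' Exploratory screen over all `choose(k, 2)` site pairs, uncorrected.
#'
#' @param ps A `pattern_set`.
#' @return Tibble with `site_a`, `site_b` (window site indices), `pos_a`,
#'   `pos_b` (0-based region offsets), `chi2`, `p_value`.
#' @export
cpg_dependency_all <- function(ps) {
  k <- length(ps$window$sites)
  if (k < 2L || ps$n == 0L) {
    return(tibble(site_a = integer(), site_b = integer(), pos_a = integer(),
                  pos_b = integer(), chi2 = numeric(), p_value = numeric()))
  }
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    d <- cpg_pair_dependency(ps, pairs[1L, j], pairs[2L, j])
    tibble(site_a = pairs[1L, j], site_b = pairs[2L, j],
           pos_a = ps$window$sites[pairs[1L, j]], pos_b = ps$window$sites[pairs[2L, j]],
           chi2 = d$chi2, p_value = d$p_value)
  })
  bind_rows(rows)
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %s [%d, %d): n = %d reads, %d pattern(s), p0 = %s\n",
              x$region_name, x$window$start, x$window$end, x$n,
              nrow(x$patterns),
              if (is.na(x$p0)) "NA" else format(x$p0, digits = 4)))
  if (nrow(x$patterns) > 0L) print(x$patterns, ...)
  invisible(x)
}

#' Tidy a pattern set into its pattern table
#'
#' @param x A `pattern_set`.
#' @param alpha Threshold used for the `significant` flag column.
#' @param ... Unused.
#' @return Tibble of patterns with region/window metadata and a
#'   `significant` flag, sorted in descending significance.
#' @export
tidy.pattern_set <- function(x, alpha = 0.05, ...) {
  pat <- x$patterns
  if (nrow(pat) == 0L) {
    return(tibble(region_name = character(), window_start = integer(),
                  window_end = integer(), signature = character(),
                  support = integer(), fraction = numeric(), z = numeric(),
                  p_value = numeric(), significant = logical()))
  }
  out <- tibble(
    region_name = x$region_name,
    window_start = x$window$start,
    window_end = x$window$end,
    signature = pat$signature,
    support = pat$support,
    fraction = pat$fraction,
    z = pat$z,
    p_value = pat$p_value,
    significant = pat$p_value < alpha
  )
  out[order(-out$z, -out$support, out$signature), , drop = FALSE]
}

#' One-row summary of a pattern set
#'
#' @param x A `pattern_set`.
#' @param alpha Significance threshold for the count of significant patterns.
#' @param ... Unused.
#' @return One-row tibble: region, window, `n`, `n_patterns`, `p0`,
#'   `n_significant`.
#' @export
glance.pattern_set <- function(x, alpha = 0.05, ...) {
  tibble(
    region_name = x$region_name,
    window_start = x$window$start,
    window_end = x$window$end,
    n = x$n,
    n_patterns = nrow(x$patterns),
    p0 = x$p0,
    n_significant = if (nrow(x$patterns)) sum(x$patterns$p_value < alpha) else 0L
  )
}

# internal: per-site methylation level over window sites from covering reads
site_levels <- function(covering, window) {
  k <- length(window$sites)
  if (nrow(covering) == 0L) return(rep(NA_real_, k))
  vapply(seq_len(k), function(i) {
    ch <- substring(covering$signature, i, i)
    mean(ch == "M")
  }, numeric(1))
}
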
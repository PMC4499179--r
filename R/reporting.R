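# Text encoding of one pattern row (fixed-width, one cell per window
# position): a methylated CpG occupies "@@", an unmethylated CpG "**",
# every non-CpG position "-", and a variant allele is shown as its base.

# internal: render one signature into window-width cells
pattern_cells <- function(signature, window, mutations = NULL) {
  width <- window$end - window$start
  cells <- rep("-", width)
  for (i in seq_along(window$sites)) {
    rel <- window$sites[i] - window$start + 1L
    ch <- if (substring(signature, i, i) == "M") "@" else "*"
    cells[rel] <- ch
    cells[rel + 1L] <- ch
  }
  if (!is.null(mutations) && nrow(mutations) > 0L) {
    for (j in seq_len(nrow(mutations))) {
      rel <- mutations$position[j] - window$start + 1L
      if (rel >= 1L && rel <= width) cells[rel] <- mutations$var_allele[j]
    }
  }
  paste(cells, collapse = "")
}

#' Render significant patterns as a fixed-width text report
#'
#' One line per significant pattern, in descending significance, each cell
#' aligned to a window reference position: `@@` marks a methylated CpG,
#' `**` an unmethylated CpG, `-` a non-CpG position, and a variant allele is
#' shown as its base character. Each line is suffixed by tab-separated
#' support count and percentage. The header gives the region name and
#' 1-based inclusive window coordinates.
#'
#' @param ps A `pattern_set`.
#' @param mutations Optional mutation tibble (for allele-group reports whose
#'   reads carry the variant base).
#' @param alpha,min_fraction Passed to [significant_patterns()].
#' @return Character vector of report lines.
#' @export
render_text <- function(ps, mutations = NULL, alpha = 0.05, min_fraction = NULL) {
  stopifnot(inherits(ps, "pattern_set"))
  w <- ps$window
  header <- sprintf("# %s %d-%d (n=%d reads, %d patterns)",
                    ps$region_name, w$start + 1L, w$end, ps$n, nrow(ps$patterns))
  sig <- significant_patterns(ps, alpha = alpha, min_fraction = min_fraction)
  if (nrow(sig) == 0L) return(c(header, "# no significant patterns"))
  lines <- vapply(seq_len(nrow(sig)), function(i) {
    sprintf("%s\t%d\t%.1f%%",
            pattern_cells(sig$signature[i], w, mutations),
            sig$support[i], 100 * sig$fraction[i])
  }, character(1))
  c(header, lines)
}

# internal: map a 0-based region interval [a, b) to genome coordinates
region_to_genome <- function(r, a, b) {
  if (r$genome_strand == "-") {
    c(r$genome_start + r$length - b, r$genome_start + r$length - a)
  } else {
    c(r$genome_start + a, r$genome_start + b)
  }
}

#' Render significant patterns as a UCSC Genome Browser custom track
#'
#' Emits a `track` header followed by one BED12 line per significant pattern
#' (blocks mark the methylated CpG sites as 2 bp boxes; 1 bp anchor blocks
#' are added at the window boundaries where required by the BED block
#' conventions) and one BED6 summary line per CpG site whose score carries
#' the site's overall methylation level. Scores are
#' `round(fraction * 1000)`, clamped to `[0, 1000]`; all coordinates are
#' 0-based half-open per BED. Requires region genome coordinates.
#'
#' @param ps A `pattern_set`.
#' @param regions Region tibble with genome coordinates attached
#'   ([load_region_coords()]).
#' @param sample Sample label used in the track description.
#' @param alpha,min_fraction Passed to [significant_patterns()].
#' @return Character vector of track lines.
#' @export
render_track <- function(ps, regions, sample = "sample", alpha = 0.05, min_fraction = NULL) {
  stopifnot(inherits(ps, "pattern_set"))
  r <- region_row(regions, ps$region_name)
  if (is.na(r$chrom)) {
    abort_mc(paste0("region '%s' has no genome coordinates; supply a coordinates ",
                    "file via load_region_coords() to enable track output"), ps$region_name)
  }
  w <- ps$window
  span <- region_to_genome(r, w$start, w$end)
  header <- sprintf('track name="%s" description="methylation patterns %s (%s)" useScore=1 db=%s',
                    ps$region_name, ps$region_name, sample, r$assembly)
  sig <- significant_patterns(ps, alpha = alpha, min_fraction = min_fraction)
  pat_lines <- character(0)
  if (nrow(sig) > 0L) {
    pat_lines <- vapply(seq_len(nrow(sig)), function(i) {
      meth <- which(strsplit(sig$signature[i], "")[[1L]] == "M")
      blocks <- lapply(w$sites[meth], function(s) region_to_genome(r, s, s + 2L))
      starts <- sort(vapply(blocks, `[`, numeric(1), 1L)) - span[1L]
      sizes <- rep(2L, length(starts))
      # anchor blocks so the first block starts at chromStart and the last
      # ends at chromEnd, as BED12 requires
      if (length(starts) == 0L || starts[1L] > 0L) {
        starts <- c(0L, starts); sizes <- c(1L, sizes)
      }
      last_end <- starts[length(starts)] + sizes[length(sizes)]
      if (last_end < span[2L] - span[1L]) {
        starts <- c(starts, span[2L] - span[1L] - 1L); sizes <- c(sizes, 1L)
      }
      score <- max(0L, min(1000L, round(sig$fraction[i] * 1000)))
      sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t%d\t%s\t%s",
              r$chrom, span[1L], span[2L],
              sprintf("pattern_%d_%.1f%%", i, 100 * sig$fraction[i]),
              score, r$genome_strand, span[1L], span[2L],
              length(starts),
              paste0(paste(sizes, collapse = ","), ","),
              paste0(paste(starts, collapse = ","), ","))
    }, character(1))
  }
  # per-site summary: overall methylation level as the score
  site_lines <- character(0)
  if (ps$n > 0L && length(w$sites) > 0L) {
    lv <- vapply(seq_along(w$sites), function(i) {
      ch <- substring(ps$patterns$signature, i, i)
      sum(ps$patterns$support[ch == "M"]) / ps$n
    }, numeric(1))
    site_lines <- vapply(seq_along(w$sites), function(i) {
      g <- region_to_genome(r, w$sites[i], w$sites[i] + 2L)
      sprintf("%s\t%d\t%d\tsite_%d_level_%.3f\t%d\t%s",
              r$chrom, g[1L], g[2L], i, lv[i],
              max(0L, min(1000L, round(lv[i] * 1000))), r$genome_strand)
    }, character(1))
  }
  c(header, pat_lines, site_lines)
}

#' Plot a pattern set
#'
#' One row per significant pattern (filled circle = methylated CpG, open
#' circle = unmethylated; a blue bar marks variant-allele positions; the
#' support percentage labels the row) plus a bottom summary row of circles
#' coloured from green (low) to red (high) by per-site methylation level.
#' The x axis shows genome coordinates when the region has them, else
#' region offsets. Pattern percentages need not sum to 100 because not all
#' reads belong to a significant pattern.
#'
#' @param object A `pattern_set`.
#' @param regions Optional region tibble; supplies genome coordinates for
#'   the x axis and labels.
#' @param mutations Optional mutation tibble; variant positions are drawn as
#'   blue bars.
#' @param alpha,min_fraction Passed to [significant_patterns()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pattern_set <- function(object, regions = NULL, mutations = NULL,
                                 alpha = 0.05, min_fraction = NULL, ...) {
  ps <- object
  w <- ps$window
  sig <- significant_patterns(ps, alpha = alpha, min_fraction = min_fraction)
  k <- length(w$sites)
  coord_of <- function(offsets) {
    if (!is.null(regions)) {
      r <- region_row(regions, ps$region_name)
      if (!is.na(r$chrom)) {
        return(if (r$genome_strand == "-") r$genome_start + r$length - 1L - offsets
               else r$genome_start + offsets)
      }
    }
    offsets
  }
  x <- coord_of(w$sites)
  m <- nrow(sig)
  rows <- if (m > 0L) {
    bind_rows(lapply(seq_len(m), function(i) {
      tibble(x = x, y = m - i + 1,
             methylated = strsplit(sig$signature[i], "")[[1L]] == "M")
    }))
  } else tibble(x = numeric(), y = numeric(), methylated = logical())
  lv <- if (ps$n > 0L && k > 0L) {
    vapply(seq_len(k), function(i) {
      ch <- substring(ps$patterns$signature, i, i)
      sum(ps$patterns$support[ch == "M"]) / ps$n
    }, numeric(1))
  } else rep(NA_real_, k)
  summary_row <- tibble(x = x, y = 0, level = lv)
  labels <- if (m > 0L) {
    tibble(x = max(x) + 0.05 * max(diff(range(x)), 4), y = m - seq_len(m) + 1,
           label = sprintf("%.1f%% (n=%d)", 100 * sig$fraction, sig$support))
  } else tibble(x = numeric(), y = numeric(), label = character())
  cap <- if (m > 0L) {
    "Percentages of significant patterns need not sum to 100%."
  } else "No significant patterns."
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = rows,
                        ggplot2::aes(x = .data$x, y = .data$y, fill = .data$methylated),
                        shape = 21, size = 5, colour = "black", show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    ggplot2::geom_point(data = summary_row,
                        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$level),
                        shape = 19, size = 5) +
    ggplot2::scale_colour_gradient(low = "green3", high = "red", limits = c(0, 1),
                                   name = "methylation") +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       hjust = 0, size = 3) +
    ggplot2::scale_y_continuous(breaks = c(0, seq_len(max(m, 1L))),
                                labels = c("level", if (m > 0L) paste0("pattern ", seq_len(m)) else "")) +
    ggplot2::labs(x = if (!is.null(regions)) "position" else "region offset",
                  y = NULL,
                  title = sprintf("%s [%d-%d], n = %d reads", ps$region_name,
                                  w$start + 1L, w$end, ps$n),
                  caption = cap) +
    ggplot2::expand_limits(x = max(x) + 0.25 * max(diff(range(x)), 4)) +
    ggplot2::theme_minimal()
  if (!is.null(mutations) && nrow(mutations) > 0L) {
    mut <- mutations[mutations$region_name == ps$region_name &
                       mutations$position >= w$start & mutations$position < w$end, ,
                     drop = FALSE]
    if (nrow(mut) > 0L) {
      p <- p + ggplot2::geom_vline(xintercept = coord_of(mut$position),
                                   colour = "blue", linewidth = 2, alpha = 0.4)
    }
  }
  p
}

#' Write a pattern-set figure to file
#'
#' @param ps A `pattern_set`.
#' @param path Output file; format from extension unless given.
#' @param format `"png"` or `"eps"`.
#' @param width,height Figure size in inches.
#' @param ... Passed to [autoplot.pattern_set()].
#' @return `path`, invisibly.
#' @export
render_figure <- function(ps, path, format = c("png", "eps"), width = 8, height = 5, ...) {
  format <- match.arg(format)
  p <- autoplot(ps, ...)
  dev <- if (format == "eps") grDevices::cairo_ps else "png"
  ggplot2::ggsave(path, plot = p, device = dev, width = width, height = height,
                  dpi = 150)
  invisible(path)
}

#' Write a pattern table to TSV
#'
#' Columns: region, 1-based inclusive window coordinates, signature, support,
#' fraction (percent, one decimal), z and p-value (3 significant digits,
#' scientific), significant flag.
#'
#' @param ps A `pattern_set`.
#' @param path Output path.
#' @param alpha Significance threshold for the flag.
#' @return `path`, invisibly.
#' @export
write_pattern_tsv <- function(ps, path, alpha = 0.05) {
  td <- tidy(ps, alpha = alpha)
  out <- data.frame(
    region = td$region_name,
    window_start = td$window_start + 1L,
    window_end = td$window_end,
    signature = td$signature,
    support = td$support,
    percent = sprintf("%.1f", 100 * td$fraction),
    z = sprintf("%.3g", td$z),
    p_value = sprintf("%.3g", td$p_value),
    significant = td$significant
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ASM results to TSV
#'
#' One row per window CpG site and mutation, with 1-based output positions,
#' per-allele levels and categories, the candidate flag and any dbSNP ID.
#'
#' @param asm_list List of `asm_result` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asm_tsv <- function(asm_list, path) {
  if (inherits(asm_list, "asm_result")) asm_list <- list(asm_list)
  rows <- lapply(asm_list, function(a) {
    td <- tidy(a)
    td$mutation_position <- td$mutation_position + 1L
    td$position <- td$position + 1L
    td$var_fraction <- a$mutation$var_fraction
    td$is_candidate <- a$is_candidate
    td$status <- a$status
    td$dbsnp_id <- if ("dbsnp_id" %in% names(a$mutation)) a$mutation$dbsnp_id else NA_character_
    td
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0L) {
    out$level_ref <- sprintf("%.3f", out$level_ref)
    out$level_var <- sprintf("%.3f", out$level_var)
    out$difference <- sprintf("%.3f", out$difference)
    out$var_fraction <- sprintf("%.3f", out$var_fraction)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
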
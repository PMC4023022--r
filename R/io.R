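# Readers, writers, reverse-keying and ranked reporting. Two input
# layouts are accepted: a respondent x item table of raw Likert answers
# (CSV/TSV, header row of item ids, optional leading respondent-id
# column) and a per-item counts table (item, c1..cm) — every analysis in
# the package depends only on per-item counts.

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a respondent-by-item Likert response table
#'
#' Parses a CSV/TSV whose header row holds item ids and whose cells hold
#' integer responses in 1..m (missing cells allowed). A leading
#' respondent-identifier column (named `id`/`respondent`, or
#' non-numeric) is ignored. Items listed in `key` are reverse-keyed,
#' `x -> (m+1) - x`, before counting; missing cells are dropped item by
#' item, so each item's N is the number of respondents who answered it.
#'
#' @param path Path to the CSV/TSV file.
#' @param m Number of response categories (default 5).
#' @param key Character vector of reverse-keyed item ids (see
#'   [read_key_list()]); unknown ids produce a warning.
#' @param sep Field separator; inferred from the file extension when
#'   NULL.
#' @return A named list of [response_counts], one per item column.
#' @export
read_response_table <- function(path, m = 5, key = NULL, sep = NULL) {
  tab <- read.table(path, header = TRUE, sep = infer_sep(path, sep),
                    na.strings = c("NA", ""), check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) > 0) {
    first <- tab[[1]]
    if (tolower(names(tab)[1]) %in% c("id", "respondent", "subject") ||
        is.character(first)) {
      tab <- tab[, -1, drop = FALSE]
    }
  }
  if (ncol(tab) == 0) stop("no item columns found in ", path)
  if (!is.null(key)) {
    unknown <- setdiff(key, names(tab))
    if (length(unknown) > 0) {
      warning("reverse-key list names unknown item(s): ",
              paste(unknown, collapse = ", "))
    }
  }
  out <- vector("list", ncol(tab))
  names(out) <- names(tab)
  for (j in seq_along(tab)) {
    x <- tab[[j]]
    bad <- which(!is.na(x) & (x != round(x) | x < 1 | x > m))
    if (length(bad) > 0) {
      stop(sprintf(
        "response out of range 1..%d in column '%s', row %d (value %s)",
        m, names(tab)[j], bad[1], format(x[bad[1]])))
    }
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("item '", names(tab)[j], "' has no responses")
    if (names(tab)[j] %in% key) x <- (m + 1) - x
    out[[j]] <- response_counts(tabulate(x, nbins = m),
                                item_id = names(tab)[j], m = m)
  }
  out
}

#' Read a reverse-key list
#'
#' Plain text, one item id per line; blank lines and lines starting with
#' `#` are ignored.
#'
#' @param path File path.
#' @return Character vector of item ids.
#' @export
read_key_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Reverse-key a counts vector
#'
#' Reversing a keyed item at the response level, `x -> (m+1) - x`, is
#' equivalent to reversing its category counts; applying it twice
#' restores the original item.
#'
#' @param counts A [response_counts] object or numeric counts vector.
#' @return The reverse-keyed [response_counts].
#' @export
reverse_key_counts <- function(counts) {
  obs <- as_counts(counts)
  response_counts(rev(unname(obs$counts)), item_id = obs$item_id,
                  m = obs$m)
}

#' Read / write a per-item counts table
#'
#' TSV with columns `item`, `c1`..`cm`; counts may be real-valued
#' (expected counts). The writer preserves full double precision so that
#' simulate -> write -> read -> fit reproduces the in-memory fit exactly.
#'
#' @param bank A list of [response_counts] (or an `"item_bank"`).
#' @param path File path.
#' @return `write_counts_table` returns `path` invisibly;
#'   `read_counts_table` returns a named list of [response_counts].
#' @export
write_counts_table <- function(bank, path) {
  if (inherits(bank, "item_bank")) bank <- bank$counts
  m <- as_counts(bank[[1]])$m
  lines <- vapply(bank, function(cnt) {
    cnt <- as_counts(cnt)
    paste(c(cnt$item_id, sprintf("%.17g", cnt$counts)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("item", paste0("c", seq_len(m))), collapse = "\t"),
               lines), path)
  invisible(path)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  m <- ncol(tab) - 1
  if (m < 2) stop("counts table needs columns item, c1..cm")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    response_counts(as.numeric(tab[i, -1]), item_id = tab[i, 1], m = m)
  })
  names(out) <- tab[[1]]
  out
}

#' Fit every item of a bank
#'
#' Runs [fit_binomial()] and [fit_mixed_binomial()] (and optionally
#' [fit_normal()]) on each item and collects the per-item
#' model-selection records consumed by [write_fit_report()] and
#' [scan_bank_bias()].
#'
#' @param bank A list of [response_counts] (or an `"item_bank"`).
#' @param normal Also fit the two-parameter normal benchmark.
#' @param ... Passed to the fitters (`guard`, `df_mode`, grid steps).
#' @return A `"bank_fits"` list, one record per item with elements
#'   `item`, `single`, `mixed` and optionally `normal`.
#' @export
fit_item_bank <- function(bank, normal = FALSE, ...) {
  if (inherits(bank, "item_bank")) bank <- bank$counts
  out <- lapply(bank, function(cnt) {
    cnt <- as_counts(cnt)
    single <- fit_binomial(cnt, ...)
    mixed <- fit_mixed_binomial(cnt, single = single, ...)
    rec <- list(item = cnt$item_id, single = single, mixed = mixed)
    if (normal) rec$normal <- fit_normal(cnt)
    rec
  })
  structure(out, class = "bank_fits")
}

#' Summarise a bank fit as a data.frame
#'
#' One row per item with the selected model's parameters and fit
#' statistics: `p_B`, `q_B`, `w` (`q_B`/`w` are NA when the single
#' binomial was retained), `chi2`, `p_value`, `improvement_pct`,
#' `selected`.
#'
#' @param x A `"bank_fits"` object from [fit_item_bank()].
#' @param ... Unused.
#' @return A data.frame, one row per item.
#' @export
as.data.frame.bank_fits <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(item = character(0), p_B = numeric(0),
                      q_B = numeric(0), w = numeric(0),
                      chi2 = numeric(0), p_value = numeric(0),
                      improvement_pct = numeric(0),
                      selected = logical(0),
                      chi2_single = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(x, function(rec) {
    mx <- rec$mixed
    sel <- mx$selected
    data.frame(
      item = rec$item,
      p_B = if (sel) mx$p_B else mx$single$p_B,
      q_B = if (sel) mx$q_B else NA_real_,
      w = if (sel) mx$w else NA_real_,
      chi2 = if (sel) mx$chi2 else mx$single$chi2,
      p_value = if (sel) mx$p_value else mx$single$p_value,
      improvement_pct = mx$improvement_pct,
      selected = sel,
      chi2_single = mx$single$chi2,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a ranked per-item fit report
#'
#' Items are ranked by the selected model's chi-square, ascending (best
#' approximated first). Columns: `Rnk`, `item`, `facet`, `p_B`, `q_B`,
#' `w`, `chi2`, `impr_pct`; parameters are printed to two decimals and
#' `q_B`/`w` are left blank for items where the mixture improved the
#' single-binomial fit by less than 5%. When item metadata is supplied, a
#' per-domain mean-chi-square summary block is appended as `#`-prefixed
#' comment lines.
#'
#' @param fits A `"bank_fits"` object (or its data.frame form).
#' @param path Output TSV path.
#' @param metadata Optional data.frame with columns `item_id` and
#'   `facet` (facet codes like `N1`, `E5`; the domain is the facet's
#'   first letter).
#' @return The ranked data.frame, invisibly.
#' @export
write_fit_report <- function(fits, path, metadata = NULL) {
  df <- if (inherits(fits, "bank_fits")) as.data.frame(fits) else fits
  if (!is.null(metadata)) {
    idx <- match(df$item, metadata$item_id)
    df$facet <- metadata$facet[idx]
  } else if (is.null(df$facet)) {
    df$facet <- rep(NA_character_, nrow(df))
  }
  if (nrow(df) > 0) {
    df <- df[order(df$chi2, df$item), ]
    df$Rnk <- seq_len(nrow(df))
  } else {
    df$Rnk <- integer(0)
  }
  fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  out <- data.frame(
    Rnk = df$Rnk,
    item = df$item,
    facet = ifelse(is.na(df$facet), "", df$facet),
    p_B = fmt2(df$p_B),
    q_B = fmt2(df$q_B),
    w = fmt2(df$w),
    chi2 = sprintf("%.2f", df$chi2),
    impr_pct = sprintf("%.1f", df$improvement_pct),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata) && nrow(df) > 0) {
    summ <- domain_chi2_summary(df, metadata)
    writeLines("# domain mean_chi2 n_items", con)
    writeLines(sprintf("# %s\t%.2f\t%d", summ$domain, summ$mean_chi2,
                       summ$n_items), con)
  }
  invisible(df)
}

#' Mean chi-square by personality domain
#'
#' Groups items by the first letter of their facet code and averages the
#' selected model's chi-square, mirroring per-dimension misfit summaries.
#'
#' @param fits A `"bank_fits"` object or its data.frame form.
#' @param metadata data.frame with columns `item_id`, `facet`.
#' @return A data.frame with `domain`, `mean_chi2`, `n_items`.
#' @export
domain_chi2_summary <- function(fits, metadata) {
  df <- if (inherits(fits, "bank_fits")) as.data.frame(fits) else fits
  facet <- metadata$facet[match(df$item, metadata$item_id)]
  domain <- substr(facet, 1, 1)
  keep <- !is.na(domain) & nzchar(domain)
  agg <- aggregate(df$chi2[keep], by = list(domain = domain[keep]),
                   FUN = mean)
  names(agg)[2] <- "mean_chi2"
  agg$n_items <- as.integer(table(domain[keep])[agg$domain])
  agg
}

#' Write per-item fit records as JSON
#'
#' @param fits A `"bank_fits"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fits, path) {
  df <- as.data.frame(fits)
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a noise-tolerance curve as TSV
#'
#' The curve table is written as TSV and the full configuration is
#' echoed alongside as JSON (`<path>.json`).
#'
#' @param nc A `"noise_curve"` from [noise_misfit_curve()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_noise_curve <- function(nc, path) {
  write.table(nc$curve, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- c(nc$config, list(critical = nc$critical))
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
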
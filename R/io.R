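# Tab-separated readers and writers for all table kinds: paired allele
# signals, genotype calls, normalized tracks, region specifications and
# evaluation reports. Delimiter is tab, missing token "NA", header required;
# unknown columns are preserved on passthrough. Reading supports fixed-size
# chunks so that memory is bounded by the chunk size, not the file.

PAIRED_COLUMNS <- c("chromosome", "position", "theta_a_normal",
                    "theta_b_normal", "theta_a_tumor", "theta_b_tumor")

check_schema <- function(header, required, path) {
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop_bafnorm(sprintf("%s: missing required column(s): %s", path,
                         paste(missing, collapse = ", ")),
                 "bafnorm_schema_error")
  }
}

chunk_to_pair <- function(df, path, sort_positions) {
  num <- c("position", "theta_a_normal", "theta_b_normal", "theta_a_tumor",
           "theta_b_tumor")
  malformed <- rep(FALSE, nrow(df))
  for (col in num) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    malformed <- malformed | (is.na(v) & !is.na(raw) &
                                trimws(raw) != "NA" & trimws(raw) != "")
    df[[col]] <- v
  }
  if (any(malformed)) {
    log_msg("warn", sprintf("%s: dropped %d malformed row(s)", path,
                            sum(malformed)))
    df <- df[!malformed, , drop = FALSE]
  }
  if (!check_sorted_positions(df$chromosome, df$position)) {
    if (sort_positions) {
      df <- df[order(df$chromosome, df$position), , drop = FALSE]
    } else {
      stop_bafnorm(sprintf(
        "%s: positions not strictly increasing within chromosome (use sort_positions = TRUE)",
        path), "bafnorm_unsorted_positions")
    }
  }
  paired_snps_from_intensities(
    df$chromosome, df$position,
    df$theta_a_normal, df$theta_b_normal,
    df$theta_a_tumor, df$theta_b_tumor)
}

#' Read paired tumor-normal allele signals from TSV
#'
#' Expects a tab-separated file with header columns `chromosome`,
#' `position`, `theta_a_normal`, `theta_b_normal`, `theta_a_tumor`,
#' `theta_b_tumor` (missing token `NA`). Malformed rows are counted,
#' reported and dropped.
#'
#' @param path File path.
#' @param chunk_size Maximum SNPs held in memory at once. With the default
#'   `Inf` a single [paired_snps()] table is returned; with a finite value,
#'   either a list of chunk tables (in genomic file order) or — when
#'   `callback` is given — each chunk is passed to `callback(chunk)` and
#'   only the callback results are kept.
#' @param callback Optional function applied to each chunk.
#' @param sort_positions Sort rows by position within chromosome instead of
#'   failing on unsorted input.
#' @return A `paired_snps` table, a list of them, or the list of callback
#'   results.
#' @export
read_paired_signals <- function(path, chunk_size = Inf, callback = NULL,
                                sort_positions = FALSE) {
  if (!file.exists(path)) {
    stop_bafnorm(sprintf("file not found: %s", path), "bafnorm_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  check_schema(header, PAIRED_COLUMNS, path)
  if (!is.finite(chunk_size)) {
    df <- utils::read.delim(path, colClasses = "character",
                            na.strings = NULL)
    return(chunk_to_pair(df, path, sort_positions))
  }
  con <- file(path, "r")
  on.exit(close(con))
  readLines(con, n = 1L)  # consume header
  chunks <- list()
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (!length(lines)) break
    df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            header = FALSE, colClasses = "character",
                            na.strings = NULL)
    names(df) <- header
    chunk <- chunk_to_pair(df, path, sort_positions)
    chunks[[length(chunks) + 1L]] <-
      if (is.null(callback)) chunk else callback(chunk)
  }
  chunks
}

#' Write paired allele signals to TSV
#'
#' Inverse of [read_paired_signals()]: the `(theta, beta)` representation is
#' converted back to allele intensities (SNPs with `theta = 0` and undefined
#' `beta` are written as `(0, 0)`).
#'
#' @param pair A [paired_snps()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paired_signals <- function(pair, path) {
  stopifnot(inherits(pair, "paired_snps"))
  to_ab <- function(theta, beta) {
    beta[is.na(beta) & !is.na(theta) & theta == 0] <- 0
    data.frame(a = theta * (1 - beta), b = theta * beta)
  }
  n <- to_ab(pair$theta_n, pair$beta_n)
  t <- to_ab(pair$theta_t, pair$beta_t)
  out <- data.frame(chromosome = pair$chromosome, position = pair$position,
                    theta_a_normal = n$a, theta_b_normal = n$b,
                    theta_a_tumor = t$a, theta_b_tumor = t$b)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

GENOTYPE_TO_MU <- c(AA = 0, AB = 0.5, BB = 1, A = 0, B = 1, NC = NA_real_)

#' Read genotype calls from TSV
#'
#' Columns: `snp_id` (optional), `chromosome`, `position`, `call` (one of
#' `AA`, `AB`, `BB`, `A`, `B`, `NC`), `confidence`. Calls are mapped to
#' `mu_hat` 0, 0.5, 1 (or missing for `NC`).
#'
#' @param path File path.
#' @return A `"genotype_calls"` object with `source = "external"`.
#' @export
read_genotype_calls <- function(path) {
  if (!file.exists(path)) {
    stop_bafnorm(sprintf("file not found: %s", path), "bafnorm_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(chromosome = "character"))
  check_schema(names(df), c("chromosome", "position", "call", "confidence"),
               path)
  bad <- !(df$call %in% names(GENOTYPE_TO_MU))
  if (any(bad)) {
    stop_bafnorm(sprintf("%s: unknown genotype code(s): %s", path,
                         paste(unique(df$call[bad]), collapse = ", ")),
                 "bafnorm_schema_error")
  }
  structure(list(
    mu_hat = unname(GENOTYPE_TO_MU[df$call]),
    confidence = as.numeric(df$confidence),
    thresholds = numeric(0), source = "external",
    chromosome = as.character(df$chromosome), position = df$position
  ), class = "genotype_calls")
}

#' Write genotype calls to TSV
#'
#' @param calls A `"genotype_calls"` object with coordinates.
#' @param path Output file path.
#' @param hemizygous Encode calls as `A`/`B` instead of `AA`/`AB`/`BB`.
#' @return `path`, invisibly.
#' @export
write_genotype_calls <- function(calls, path, hemizygous = FALSE) {
  stopifnot(inherits(calls, "genotype_calls"),
            !is.null(calls$chromosome), !is.null(calls$position))
  code <- if (hemizygous) {
    ifelse(is.na(calls$mu_hat), "NC", ifelse(calls$mu_hat == 0, "A", "B"))
  } else {
    ifelse(is.na(calls$mu_hat), "NC",
           c("AA", "AB", "BB")[match(calls$mu_hat, c(0, 0.5, 1))])
  }
  out <- data.frame(snp_id = seq_along(calls$mu_hat),
                    chromosome = calls$chromosome,
                    position = calls$position, call = code,
                    confidence = calls$confidence)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a TumorBoost-normalized track to TSV
#'
#' Emits the paired signals plus `mu_hat`, `beta_t_norm`, `eta` and
#' `normalized_flag`; optionally the corrected allele intensities
#' `theta_a_norm`, `theta_b_norm` ([dual_intensity_form()]).
#'
#' @param fit A `"tumorboost"` fit.
#' @param path Output file path.
#' @param intensities Also write the corrected allele intensities.
#' @return `path`, invisibly.
#' @export
write_normalized_track <- function(fit, path, intensities = FALSE) {
  stopifnot(inherits(fit, "tumorboost"))
  out <- data.frame(
    chromosome = fit$data$chromosome, position = fit$data$position,
    theta_n = fit$data$theta_n, beta_n = fit$data$beta_n,
    theta_t = fit$data$theta_t, beta_t = fit$data$beta_t,
    mu_hat = fit$mu_hat, beta_t_norm = fit$beta_t_norm, eta = fit$eta,
    normalized_flag = fit$normalized)
  if (intensities) {
    ok <- !is.na(fit$beta_t_norm)
    out$theta_a_norm <- out$theta_b_norm <- NA_real_
    ab <- dual_intensity_form(fit$data$theta_t[ok], fit$beta_t_norm[ok])
    out$theta_a_norm[ok] <- ab$theta_a
    out$theta_b_norm[ok] <- ab$theta_b
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a normalized track written by [write_normalized_track()]
#'
#' @param path File path.
#' @return Data frame with the track columns.
#' @export
read_normalized_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(chromosome = "character"))
  check_schema(names(df), c("chromosome", "position", "theta_n", "beta_n",
                            "theta_t", "beta_t", "mu_hat", "beta_t_norm",
                            "eta", "normalized_flag"), path)
  df
}

parse_pcn <- function(x) {
  parts <- strsplit(gsub("[()\\s]", "", x, perl = TRUE), ",")[[1]]
  if (length(parts) != 2) {
    stop_bafnorm(sprintf("cannot parse PCN state '%s' (expected 'c1,c2')", x),
                 "bafnorm_schema_error")
  }
  pcn_state(as.numeric(parts[1]), as.numeric(parts[2]))
}

#' Read change-point region specifications from TSV
#'
#' Columns: `label`, `chr`, `start`, `end`, `changepoint`, `safety`,
#' `pcn1`, `pcn2`. Coordinates may be in Mb (default, converted to bp) or
#' bp. `safety` is the total width of the safety region centered on the
#' change point (margin per side is half of it). PCN states are written as
#' `c1,c2` (parentheses allowed).
#'
#' @param path File path.
#' @param units `"Mb"` (default) or `"bp"`.
#' @return Named list of [changepoint_spec()] objects.
#' @export
read_region_specs <- function(path, units = c("Mb", "bp")) {
  units <- match.arg(units)
  f <- if (units == "Mb") 1e6 else 1
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(chr = "character",
                                            pcn1 = "character",
                                            pcn2 = "character"))
  check_schema(names(df), c("label", "chr", "start", "end", "changepoint",
                            "safety", "pcn1", "pcn2"), path)
  specs <- lapply(seq_len(nrow(df)), function(i) {
    changepoint_spec(df$label[i], df$chr[i], df$start[i] * f, df$end[i] * f,
                     df$changepoint[i] * f, df$safety[i] * f / 2,
                     parse_pcn(df$pcn1[i]), parse_pcn(df$pcn2[i]))
  })
  names(specs) <- df$label
  specs
}

#' Write change-point region specifications to TSV
#'
#' @param specs List of [changepoint_spec()] objects.
#' @param path Output file path.
#' @param units `"Mb"` (default) or `"bp"`.
#' @return `path`, invisibly.
#' @export
write_region_specs <- function(specs, path, units = c("Mb", "bp")) {
  units <- match.arg(units)
  f <- if (units == "Mb") 1e6 else 1
  out <- do.call(rbind, lapply(specs, function(sp) {
    data.frame(label = sp$label, chr = sp$chromosome,
               start = sp$region_start / f, end = sp$region_end / f,
               changepoint = sp$changepoint / f,
               safety = 2 * sp$safety_margin / f,
               pcn1 = sprintf("%g,%g", sp$state1[["c1"]], sp$state1[["c2"]]),
               pcn2 = sprintf("%g,%g", sp$state2[["c1"]], sp$state2[["c2"]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write an evaluation report to TSV
#'
#' @param report Data frame from [evaluate_changepoint()] or
#'   [evaluate_pair()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
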
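#' Read a per-sample methylation table
#'
#' Reads a CSV with one row per individual: required columns `sample_id`,
#' `sex`, `age`, plus one percent-methylation column per panel site (canonical
#' `GENE_ordinal` names or panel aliases). Validation is total: every
#' offending cell is reported with its row number, and no row is silently
#' dropped. Missing methylation values (`NA`/empty) are allowed and flagged
#' with a message; such samples are later excluded from clocks that need the
#' missing site.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param panel A [cpg_panel()]; defaults to [default_cpg_panel()]. Sites
#'   absent from the file are ignored with a message; at least one panel site
#'   column must be present.
#' @return A data frame with columns `sample_id`, `sex` (normalized to
#'   `"female"`/`"male"`/`"unknown"`), `age`, and one numeric column per panel
#'   site found in the file.
#' @export
read_samples <- function(path, panel = default_cpg_panel()) {
  if (!file.exists(path)) stop("sample table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(raw) <- resolve_site_names(names(raw), panel)

  required <- c("sample_id", "sex", "age")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("sample table format error: missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  site_cols <- intersect(names(raw), panel$site_id)  # keep file order
  if (!length(site_cols)) {
    stop("sample table format error: no panel site columns found (expected ",
         paste(panel$site_id, collapse = ", "), ")", call. = FALSE)
  }
  absent <- setdiff(panel$site_id, site_cols)
  if (length(absent)) {
    message("panel site(s) not in table, ignored: ",
            paste(absent, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    stop("sample table is empty (no data rows)", call. = FALSE)
  }

  samples <- raw[c(required, site_cols)]
  samples$sex <- normalize_sex(samples$sex)
  samples$age <- suppressWarnings(as.numeric(samples$age))
  for (s in site_cols) {
    samples[[s]] <- suppressWarnings(as.numeric(samples[[s]]))
  }

  errs <- validate_samples(samples, site_cols, raw)
  if (length(errs)) {
    stop("sample table validation failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  n_missing <- sum(is.na(as.matrix(samples[site_cols])))
  if (n_missing > 0) {
    message(n_missing, " missing methylation value(s) flagged; affected ",
            "samples will be excluded from clocks that require those sites")
  }
  samples
}

# row-located validation messages; `raw` keeps the pre-coercion cells so a
# non-numeric age is reported as a format problem, not as NA
validate_samples <- function(samples, site_cols, raw) {
  errs <- character(0)
  add <- function(row, msg) sprintf("row %d: %s", row, msg)
  for (i in seq_len(nrow(samples))) {
    id <- samples$sample_id[i]
    if (is.na(id) || !nzchar(id)) {
      errs <- c(errs, add(i, "empty sample_id"))
    }
    a <- samples$age[i]
    if (is.na(a)) {
      errs <- c(errs, add(i, sprintf("sample '%s': age '%s' is not numeric",
                                     id, raw$age[i])))
    } else if (a < 0 || a > 130) {
      errs <- c(errs, add(i, sprintf(
        "sample '%s': age %g outside [0, 130]", id, a)))
    }
    for (s in site_cols) {
      m <- samples[[s]][i]
      raw_m <- raw[[s]][i]
      raw_missing <- is.na(raw_m) || (is.character(raw_m) && !nzchar(raw_m))
      if (is.na(m)) {
        if (!raw_missing) {
          errs <- c(errs, add(i, sprintf(
            "sample '%s', site %s: value '%s' is not numeric", id, s, raw_m)))
        }
      } else if (m < 0 || m > 100) {
        errs <- c(errs, add(i, sprintf(
          "sample '%s', site %s: methylation %g outside [0, 100]", id, s, m)))
      }
    }
  }
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup)) {
    errs <- c(errs, paste0("duplicate sample_id: ", paste(dup, collapse = ", ")))
  }
  errs
}

#' Normalize sex labels
#'
#' Accepts `F`/`female` and `M`/`male` case-insensitively; anything else maps
#' to `"unknown"` (kept in pooled strata, excluded from per-sex strata).
#'
#' @param x Character vector of sex labels.
#' @return Character vector over `"female"`, `"male"`, `"unknown"`.
#' @export
normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("f", "female")] <- "female"
  out[x %in% c("m", "male")] <- "male"
  out
}

#' Write a sample table
#'
#' Writes the CSV format read by [read_samples()]. Numeric columns are
#' formatted at full double precision so a read/write/read round trip is
#' bit-identical.
#'
#' @param samples Data frame as returned by [read_samples()] or
#'   [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  out <- samples
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
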
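#' Define a CpG assay site
#'
#' A site is one assayed CpG position, keyed by a short identifier in the
#' canonical form `GENE_ordinal` (e.g. `"ELOVL2_6"`), with the gene symbol and
#' the direction in which its methylation is expected to drift with age.
#'
#' @param site_id Short unique key, canonical form `GENE_ordinal`.
#' @param gene Gene symbol; defaults to the part of `site_id` before `"_"`.
#' @param expected_direction One of `"increases_with_age"`,
#'   `"decreases_with_age"`, `"unknown"`.
#' @return A one-row data frame with columns `site_id`, `gene`,
#'   `expected_direction`.
#' @seealso [cpg_panel()], [default_cpg_panel()]
#' @export
cpg_site <- function(site_id,
                     gene = sub("_.*$", "", site_id),
                     expected_direction = c("unknown",
                                            "increases_with_age",
                                            "decreases_with_age")) {
  expected_direction <- match.arg(expected_direction)
  if (!is.character(site_id) || length(site_id) != 1L || !nzchar(site_id)) {
    stop("`site_id` must be a single non-empty string", call. = FALSE)
  }
  data.frame(site_id = site_id, gene = gene,
             expected_direction = expected_direction,
             stringsAsFactors = FALSE)
}

#' Assemble a CpG panel
#'
#' @param ... One-row data frames from [cpg_site()].
#' @param aliases Optional named character vector mapping alternative column
#'   spellings to canonical site ids (e.g. `c(ELOVL26 = "ELOVL2_6")`); input
#'   tables may use either form.
#' @return A data frame of class `cpg_panel`.
#' @export
cpg_panel <- function(..., aliases = NULL) {
  sites <- do.call(rbind, list(...))
  if (is.null(sites) || nrow(sites) == 0L) {
    stop("a panel needs at least one site", call. = FALSE)
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site_id in panel: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases)))) {
      stop("`aliases` must be a named character vector", call. = FALSE)
    }
    bad <- setdiff(aliases, sites$site_id)
    if (length(bad)) {
      stop("alias targets not in panel: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  attr(sites, "aliases") <- aliases
  class(sites) <- c("cpg_panel", "data.frame")
  sites
}

#' The default four-site blood-methylation panel
#'
#' ASPA, EDARADD, ELOVL2 and PDE4C harbor the classic age-associated CpGs used
#' by small pyrosequencing clocks: ELOVL2 and PDE4C promoter methylation rises
#' with age, ASPA and EDARADD methylation falls. Aliases cover the concatenated
#' spellings (`ELOVL26` for `ELOVL2_6`, etc.) seen in some source tables,
#' including the common `EDDARAD` misspelling of EDARADD.
#'
#' @return A `cpg_panel` of four sites.
#' @export
default_cpg_panel <- function() {
  cpg_panel(
    cpg_site("ASPA_1",    expected_direction = "decreases_with_age"),
    cpg_site("EDARADD_1", expected_direction = "decreases_with_age"),
    cpg_site("ELOVL2_6",  expected_direction = "increases_with_age"),
    cpg_site("PDE4C_1",   expected_direction = "increases_with_age"),
    aliases = c(ASPA1 = "ASPA_1", EDARADD1 = "EDARADD_1",
                EDDARAD1 = "EDARADD_1", ELOVL26 = "ELOVL2_6",
                PDE4C1 = "PDE4C_1")
  )
}

# map column names through the panel's alias table; unknown names pass through
resolve_site_names <- function(nms, panel) {
  aliases <- attr(panel, "aliases")
  if (is.null(aliases)) return(nms)
  hit <- nms %in% names(aliases)
  nms[hit] <- unname(aliases[nms[hit]])
  nms
}
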
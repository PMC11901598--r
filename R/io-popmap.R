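#' Population maps
#'
#' A population map assigns every sample to a lineage (species or hybrid
#' cytotype), optionally assigns lineages to clades, and designates one focal
#' lineage -- the putative allopolyploid whose allele sharing is being
#' dissected.  It is a tibble with columns `sample`, `lineage`, `clade`
#' (`NA` allowed) and a `"focal"` attribute.
#'
#' @param x Data frame with columns `sample` and `lineage` (and optionally
#'   `clade`).
#' @param focal Label of the focal lineage; must occur in `lineage`.
#' @return A validated popmap tibble.
#' @examples
#' popmap(
#'   tibble::tibble(
#'     sample = c("x1", "x2", "b1"),
#'     lineage = c("X", "X", "B"),
#'     clade = c(NA, NA, "K1")
#'   ),
#'   focal = "X"
#' )
#' @export
popmap <- function(x, focal) {
  need <- c("sample", "lineage")
  if (!all(need %in% names(x))) {
    ps_input_error("popmap needs columns `sample` and `lineage`")
  }
  x <- as_tibble(x)
  if (!"clade" %in% names(x)) x$clade <- NA_character_
  x <- mutate(x, sample = as.character(.data$sample),
              lineage = as.character(.data$lineage),
              clade = na_if(as.character(.data$clade), ""))
  if (anyDuplicated(x$sample)) {
    ps_input_error(paste0("sample listed twice in popmap: ",
                          x$sample[duplicated(x$sample)][1]))
  }
  clade_per_lineage <- distinct(x, .data$lineage, .data$clade)
  if (anyDuplicated(clade_per_lineage$lineage)) {
    ps_input_error("a lineage is assigned to more than one clade")
  }
  if (length(focal) != 1 || !focal %in% x$lineage) {
    ps_input_error("focal lineage must be one of the assigned lineages")
  }
  attr(x, "focal") <- focal
  x[c("sample", "lineage", "clade")]
}

#' @describeIn popmap The designated focal lineage of a popmap.
#' @param pm A popmap tibble.
#' @export
focal_lineage <- function(pm) {
  focal <- attr(pm, "focal")
  if (is.null(focal)) ps_input_error("popmap has no focal lineage set")
  focal
}

#' @describeIn popmap Named list clade -> member lineages (lineages with no
#'   clade, including typically the focal, are omitted).
#' @export
lineage_clades <- function(pm) {
  cl <- distinct(pm, .data$lineage, .data$clade)
  cl <- cl[!is.na(cl$clade), , drop = FALSE]
  split(cl$lineage, cl$clade)
}

#' Read a population map file
#'
#' The file is tab-separated with a `sample<TAB>lineage[<TAB>clade]` header
#' and one directive line `#focal=<lineage>` anywhere in the file; other `#`
#' lines are treated as comments.
#'
#' @param path Path to the popmap TSV.
#' @return A popmap tibble (see [popmap()]).
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) ps_input_error(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  directive <- grep("^#focal=", lines, value = TRUE)
  if (length(directive) != 1) {
    ps_input_error(paste0(path, ": exactly one `#focal=<lineage>` directive",
                          " line is required"))
  }
  focal <- sub("^#focal=", "", directive)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2) ps_input_error(paste0(path, ": no sample rows"))
  df <- readr::read_tsv(I(paste(body, collapse = "\n")),
                        col_types = readr::cols(.default = "c"))
  popmap(df, focal = focal)
}

#' Write a population map file
#'
#' @param pm A popmap tibble.
#' @param path Output path.
#' @param provenance Optional character vector of extra comment lines.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path, provenance = NULL) {
  lines <- c(
    if (!is.null(provenance)) paste0("# ", provenance),
    paste0("#focal=", focal_lineage(pm)),
    paste(c("sample", "lineage", "clade"), collapse = "\t"),
    paste(pm$sample, pm$lineage, replace_na(pm$clade, ""), sep = "\t")
  )
  write_lines_plain(lines, path)
  invisible(path)
}
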
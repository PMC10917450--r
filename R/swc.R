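#' Read a morphology from SWC
#'
#' Parses the community-standard 7-column SWC format (`id type x y z radius
#' parent`, whitespace separated, `#` comments). Structure codes are mapped
#' 1 = soma, 2 = axon, 3 = basal, 4 = apical, anything else = custom. Node
#' ids are renumbered to 1..N in parent-before-child order on import.
#'
#' Cut-flagged terminals (incomplete ends) have no standard SWC field; this
#' package stores them in a `#cut: <ids>` header comment, which [read_swc()]
#' honours and [write_swc()] emits. The ids in the header refer to the
#' renumbered 1..N ids.
#'
#' @param file path to an SWC file, or a character vector of SWC lines.
#' @return a [morph_tree()]
#' @export
read_swc <- function(file) {
  lines <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file))
    readLines(file, warn = FALSE) else unlist(strsplit(file, "\n"))
  lines <- trimws(lines)
  cut_ids <- integer(0)
  cut_hdr <- grep("^#\\s*cut:", lines, value = TRUE)
  if (length(cut_hdr) > 0)
    cut_ids <- as.integer(unlist(regmatches(cut_hdr, gregexpr("[0-9]+", cut_hdr))))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) stop("SWC input contains no data rows")
  fields <- strsplit(body, "\\s+")
  if (any(lengths(fields) != 7))
    stop("SWC format error: every data row must have 7 columns (row ",
         which(lengths(fields) != 7)[1], " does not)")
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (any(!is.finite(m))) stop("SWC format error: non-numeric field")
  code <- as.integer(m[, 2])
  label <- ifelse(code >= 1 & code <= 4, .swc_labels[pmin(code, 4L)], "custom")
  nodes <- data.frame(id = as.integer(m[, 1]), label = label,
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = as.integer(m[, 7]),
                      cut = as.integer(m[, 1]) %in% cut_ids)
  if (any(nodes$radius <= 0))
    stop("SWC format error: non-positive radius at node(s) ",
         paste(nodes$id[nodes$radius <= 0], collapse = ", "))
  morph_tree(nodes, provenance = if (length(file) == 1 && file.exists(file))
    basename(file) else "swc-text")
}

#' Write a morphology to SWC
#'
#' Emits 7-column SWC with ids 1..N in parent-before-child order (the
#' `morph_tree` storage order). Cut-flagged terminals are recorded in a
#' `#cut: <ids>` header comment; see [read_swc()].
#'
#' @param tree a [morph_tree()]
#' @param file output path; if `NULL` the SWC text is returned as a character
#'   vector instead of being written.
#' @return invisibly, the SWC lines
#' @export
write_swc <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "morph_tree"))
  nd <- tree$nodes
  if (nrow(nd) == 0) stop("cannot write an empty tree")
  hdr <- "# SWC written by dendrepair"
  if (any(nd$cut))
    hdr <- c(hdr, paste0("#cut: ", paste(which(nd$cut), collapse = " ")))
  rows <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                  nd$id, .swc_codes[nd$label], nd$x, nd$y, nd$z,
                  nd$radius, nd$parent)
  out <- c(hdr, rows)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
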
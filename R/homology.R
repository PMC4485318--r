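# Mouse -> human identifier mapping via Homologene-format tables.

new_homology_map <- function(pairs) {
  mouse <- pairs[pairs$taxid == 10090L, ]
  human <- pairs[pairs$taxid == 9606L, ]
  if (anyDuplicated(mouse$gene_id))
    validation_error("a mouse gene id appears in more than one homology group")
  m2h <- lapply(stats::setNames(mouse$hid, mouse$gene_id),
                function(h) human$gene_id[human$hid == h])
  structure(list(pairs = pairs, mouse_to_human = m2h), class = "homology_map")
}

#' @export
print.homology_map <- function(x, ...) {
  nh <- lengths(x$mouse_to_human)
  cat(sprintf("homology_map: %d mouse genes (%d unmapped, %d one-to-many)\n",
              length(nh), sum(nh == 0L), sum(nh > 1L)))
  invisible(x)
}

#' Read a Homologene-format homology table
#'
#' Standard 6-column `homologene.data` dialect, tab-delimited, no header:
#' homology group id, taxid, gene id, gene symbol, protein gi, protein
#' accession. Only mouse (10090) and human (9606) rows are used; other taxa
#' are ignored.
#'
#' @param path File to read.
#' @return An object of class `homology_map` with the raw `pairs` and a
#'   derived `mouse_to_human` list (mouse gene id -> character vector of human
#'   gene ids, possibly empty).
#' @export
read_homologene <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 6L)
  if (length(bad))
    parse_error(sprintf("line %d: expected 6 tab-delimited columns, found %d",
                        bad[1L], length(fields[[bad[1L]]])))
  m <- do.call(rbind, fields)
  pairs <- data.frame(hid = as.integer(m[, 1L]), taxid = as.integer(m[, 2L]),
                      gene_id = m[, 3L], symbol = m[, 4L],
                      protein_gi = m[, 5L], protein_accession = m[, 6L],
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$taxid %in% c(10090L, 9606L), ]
  new_homology_map(pairs)
}

#' Build a homology map from an in-memory table
#'
#' @param table A `homology_table` data frame as produced by
#'   [generate_homology_table()].
#' @return A `homology_map`, as from [read_homologene()].
#' @export
as_homology_map <- function(table) {
  need <- c("hid", "taxid", "gene_id")
  if (!all(need %in% names(table)))
    validation_error("homology table needs columns: ", paste(need, collapse = ", "))
  new_homology_map(table[table$taxid %in% c(10090L, 9606L), ])
}

#' Map a mouse signature to human gene identifiers
#'
#' Each mouse gene is replaced by all of its human homologs with the same
#' weight. Unmapped mouse genes are dropped and counted. A human gene reached
#' from both an up- and a down-weighted mouse gene is contradictory and is
#' dropped from both sets, reported as a conflict.
#'
#' @param signature A mouse-species [gene_signature()].
#' @param map A `homology_map`.
#' @return A list with `signature` (the human [gene_signature()]) and `report`
#'   (data frame: `mouse_id`, `weight`, `human_ids` comma-joined surviving
#'   partners, `status` in `mapped`/`unmapped`/`conflict`).
#' @export
map_signature <- function(signature, map) {
  stopifnot(inherits(signature, "gene_signature"), inherits(map, "homology_map"))
  if (signature$species != "mouse")
    validation_error("map_signature expects a mouse-species signature")

  partners <- function(g) map$mouse_to_human[[g]] %||% character()
  up_h <- lapply(stats::setNames(nm = signature$up), partners)
  down_h <- lapply(stats::setNames(nm = signature$down), partners)
  conflicts <- intersect(unique(unlist(up_h)), unique(unlist(down_h)))

  report_rows <- function(hlist, weight) {
    do.call(rbind, lapply(names(hlist), function(g) {
      h <- hlist[[g]]
      kept <- setdiff(h, conflicts)
      status <- if (!length(h)) "unmapped" else if (!length(kept)) "conflict" else "mapped"
      data.frame(mouse_id = g, weight = weight,
                 human_ids = paste(kept, collapse = ","),
                 status = status, stringsAsFactors = FALSE)
    }))
  }
  report <- rbind(report_rows(up_h, 1L), report_rows(down_h, -1L))

  up_out <- setdiff(unique(unlist(up_h)), conflicts)
  down_out <- setdiff(unique(unlist(down_h)), conflicts)
  if (!length(up_out) && !length(down_out))
    abort("signature '", signature$name, "' maps to no human genes")
  prov <- sprintf("%s; mapped mouse->human (%d unmapped, %d conflicting human genes)",
                  signature$provenance, sum(report$status == "unmapped"),
                  length(conflicts))
  list(signature = gene_signature(signature$name, up = up_out, down = down_out,
                                  species = "human", provenance = prov),
       report = report)
}
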
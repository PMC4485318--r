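#' Construct a signed gene signature
#'
#' A signature is a named pair of disjoint gene sets: `up` genes carry weight
#' +1 in the plasticity score and `down` genes weight -1.
#'
#' @param name Signature name.
#' @param up,down Character vectors of gene identifiers (either may be empty,
#'   but not both).
#' @param species Identifier namespace, `"mouse"` or `"human"`.
#' @param provenance Free-text note on how the signature was derived.
#' @return An object of class `gene_signature`.
#' @examples
#' gene_signature("demo", up = c("g1", "g2"), down = "g3", species = "mouse")
#' @export
gene_signature <- function(name, up = character(), down = character(),
                           species = c("mouse", "human"), provenance = "") {
  species <- match.arg(species)
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    validation_error("signature needs a non-empty name")
  both <- intersect(up, down)
  if (length(both))
    validation_error("genes in both up and down sets of '", name, "': ",
                     paste(both, collapse = ", "))
  if (length(up) + length(down) == 0L)
    validation_error("signature '", name, "' is empty")
  structure(list(name = name, up = up, down = down, species = species,
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s' (%s): %d up, %d down\n",
              x$name, x$species, length(x$up), length(x$down)))
  invisible(x)
}

#' Swap the up and down sets of a signature
#'
#' Useful for antisymmetry checks: scoring with the swapped signature negates
#' every sample score exactly.
#'
#' @param signature A `gene_signature`.
#' @return A `gene_signature` with up and down exchanged.
#' @export
swap_signature <- function(signature) {
  stopifnot(inherits(signature, "gene_signature"))
  gene_signature(signature$name, up = signature$down, down = signature$up,
                 species = signature$species,
                 provenance = paste0(signature$provenance, " [up/down swapped]"))
}

#' Read gene signatures from GMT or weighted-TSV files
#'
#' GMT has no native gene weights, so a signed-signature convention is used:
#' lines named `<base>_UP` and `<base>_DN` are merged into one signature
#' `<base>` with the respective genes as the up and down sets; a line with no
#' suffix yields an up-only signature. The weighted TSV format has a header
#' and columns `gene`, `weight` (+1 or -1) and `signature`.
#'
#' @param path File to read.
#' @param format `"gmt"` or `"weighted_tsv"`.
#' @param species Identifier namespace to stamp on the signatures.
#' @return A list of [gene_signature()] objects, named by signature.
#' @export
read_signature <- function(path, format = c("gmt", "weighted_tsv"),
                           species = c("mouse", "human")) {
  format <- match.arg(format)
  species <- match.arg(species)
  if (!file.exists(path)) abort("file not found: ", path)
  if (format == "gmt") read_signature_gmt(path, species) else read_signature_wtsv(path, species)
}

read_signature_gmt <- function(path, species) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) validation_error("no signatures in ", path)
  up <- list(); down <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      parse_error(sprintf("line %d: GMT line needs name, description and >= 1 gene", i))
    nm <- f[1L]
    genes <- unique(f[-(1:2)])
    if (grepl("_UP$", nm)) {
      base <- sub("_UP$", "", nm)
      up[[base]] <- unique(c(up[[base]], genes))
    } else if (grepl("_DN$", nm)) {
      base <- sub("_DN$", "", nm)
      down[[base]] <- unique(c(down[[base]], genes))
    } else {
      up[[nm]] <- unique(c(up[[nm]], genes))
    }
  }
  nms <- union(names(up), names(down))
  sigs <- lapply(nms, function(nm) {
    gene_signature(nm, up = up[[nm]] %||% character(),
                   down = down[[nm]] %||% character(),
                   species = species, provenance = paste0("read from ", path))
  })
  stats::setNames(sigs, nms)
}

read_signature_wtsv <- function(path, species) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "weight", "signature")
  if (!all(need %in% names(df)))
    parse_error("weighted signature TSV needs columns: ", paste(need, collapse = ", "))
  if (!all(df$weight %in% c(1, -1)))
    validation_error("signature weights must be +1 or -1")
  nms <- unique(df$signature)
  sigs <- lapply(nms, function(nm) {
    d <- df[df$signature == nm, ]
    gene_signature(nm, up = d$gene[d$weight == 1], down = d$gene[d$weight == -1],
                   species = species, provenance = paste0("read from ", path))
  })
  stats::setNames(sigs, nms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write signatures to a GMT file
#'
#' Each signature is written as an `_UP` and (if non-empty) a `_DN` line.
#'
#' @param signatures A `gene_signature` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_signature_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- character()
  for (s in signatures) {
    stopifnot(inherits(s, "gene_signature"))
    if (length(s$up))
      lines <- c(lines, paste(c(paste0(s$name, "_UP"), s$provenance, s$up), collapse = "\t"))
    if (length(s$down))
      lines <- c(lines, paste(c(paste0(s$name, "_DN"), s$provenance, s$down), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write signatures as a weighted TSV
#'
#' Columns `gene`, `weight` (+1/-1), `signature`.
#'
#' @inheritParams write_signature_gmt
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  rows <- do.call(rbind, lapply(signatures, function(s) {
    data.frame(gene = c(s$up, s$down),
               weight = rep(c(1L, -1L), c(length(s$up), length(s$down))),
               signature = s$name, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
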
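#' Default HLA gene set
#'
#' The seven classical HLA genes handled by the pipeline: the class I genes
#' A, B and C and the class II genes DRB1, DPB1, DQA1 and DQB1. All parsing
#' and voting functions take a `genes` argument so the set can be restricted
#' or extended.
#'
#' @return Character vector of gene tokens.
#' @export
hla_genes <- function() {
  c("A", "B", "C", "DRB1", "DPB1", "DQA1", "DQB1")
}

#' HLA class of a gene token
#'
#' @param gene Character vector of gene tokens (e.g. `"A"`, `"DRB1"`).
#' @return Character vector with `"I"`, `"II"` or `NA` for unknown genes.
#' @export
hla_class <- function(gene) {
  out <- rep(NA_character_, length(gene))
  out[gene %in% c("A", "B", "C")] <- "I"
  out[gene %in% c("DRB1", "DPB1", "DQA1", "DQB1")] <- "II"
  out
}

#' Parse HLA allele names from heterogeneous tool dialects
#'
#' Genotyping tools print the same allele in several dialects: with or
#' without the `HLA-` prefix, with or without the `*` gene separator, and
#' with one to four colon-separated numeric fields (`"HLA-A*02:01"`,
#' `"A02:01"`, `"DPB1:105:01"`, `"C06:103"`, `"B58"`). `parse_hla()`
#' extracts the gene token and the ordered numeric fields, left-padding
#' each field to at least two digits so that `"A2:1"` and `"A02:01"`
#' compare equal, and renders a canonical `GENE*FF:FF` form that
#' round-trips through the parser.
#'
#' @param x Character vector of allele names. `NA` entries are not allowed
#'   here; use [hla_normalize()] on table columns where `NA` means uncalled.
#' @param genes Allowed gene tokens (default [hla_genes()]).
#' @return A tibble with one row per input: `input`, `allele` (canonical
#'   rendering), `gene`, `fields` (list column of field strings) and
#'   `resolution` (number of fields, 1-4).
#' @examples
#' parse_hla(c("A01:01:03", "B58", "HLA-A*02:01"))
#' @export
parse_hla <- function(x, genes = hla_genes()) {
  if (!is.character(x)) stop("allele names must be a character vector")
  raw <- x
  x <- toupper(trimws(x))
  bad <- is.na(x) | x == ""
  if (any(bad)) {
    stop("empty or missing allele name at position ", which(bad)[1])
  }
  x <- sub("^HLA-", "", x)

  gene <- rep(NA_character_, length(x))
  rest <- rep(NA_character_, length(x))
  has_star <- grepl("*", x, fixed = TRUE)
  gene[has_star] <- sub("\\*.*$", "", x[has_star])
  rest[has_star] <- sub("^[^*]*\\*", "", x[has_star])

  # without '*': longest-prefix gene match so DQB1 is not read as gene B
  ord <- genes[order(nchar(genes), decreasing = TRUE)]
  pat <- paste0("^(", paste(ord, collapse = "|"), ")")
  hit <- regexpr(pat, x[!has_star])
  g <- rep(NA_character_, sum(!has_star))
  ok <- hit > 0
  g[ok] <- substr(x[!has_star][ok], 1L, attr(hit, "match.length")[ok])
  gene[!has_star] <- g
  rest[!has_star] <- ifelse(ok, substring(x[!has_star], nchar(g) + 1L), NA)

  unknown <- is.na(gene) | !(gene %in% genes)
  if (any(unknown)) {
    stop("unparseable allele or unknown gene: '", raw[unknown][1], "'")
  }

  rest <- sub("^:", "", rest)
  fields <- strsplit(rest, ":", fixed = TRUE)
  valid <- vapply(fields, function(f) {
    length(f) >= 1 && length(f) <= 4 && all(grepl("^[0-9]+$", f))
  }, logical(1))
  if (any(!valid)) {
    stop("unparseable allele fields in: '", raw[!valid][1], "'")
  }
  fields <- lapply(fields, function(f) {
    short <- nchar(f) < 2
    f[short] <- paste0("0", f[short])
    f
  })

  tibble::tibble(
    input = raw,
    allele = render_hla(gene, fields),
    gene = gene,
    fields = fields,
    resolution = lengths(fields)
  )
}

#' Render an allele from gene and field strings
#'
#' @param gene Character vector of gene tokens.
#' @param fields List of character vectors of numeric field strings.
#' @return Canonical `GENE*FF:FF` character vector.
#' @export
render_hla <- function(gene, fields) {
  if (!is.list(fields)) fields <- list(fields)
  paste0(gene, "*", vapply(fields, paste, character(1), collapse = ":"))
}

#' Normalize allele names to at most two-field resolution
#'
#' Truncates allele names to the first two fields (protein-level, "4-digit"
#' resolution), e.g. `A01:01:03` becomes `A*01:01`. One-field calls such as
#' `B58` cannot be up-resolved and are kept at resolution 1; by design a
#' one-field allele never compares equal to any two-field allele, so a tool
#' emitting `B58` against a benchmark `B*58:01` is counted as a miscall.
#' The function is idempotent and maps `NA` (uncalled) to `NA`.
#'
#' @inheritParams parse_hla
#' @return Character vector of canonical normalized allele names.
#' @examples
#' hla_normalize(c("A01:01:03", "A01:01", "B58", NA))
#' @export
hla_normalize <- function(x, genes = hla_genes()) {
  out <- rep(NA_character_, length(x))
  keep <- !is.na(x) & trimws(x) != ""
  if (!any(keep)) return(out)
  p <- parse_hla(x[keep], genes = genes)
  fields <- lapply(p$fields, function(f) f[seq_len(min(2L, length(f)))])
  out[keep] <- render_hla(p$gene, fields)
  out
}

#' Gene token of canonical allele names
#' @param allele Canonical allele names as produced by [hla_normalize()].
#' @return Character vector of gene tokens.
#' @export
hla_gene <- function(allele) {
  ifelse(is.na(allele), NA_character_, sub("\\*.*$", "", allele))
}

# first numeric field of a canonical allele ("B*58:01" -> "58")
hla_field1 <- function(allele) {
  sub(":.*$", "", sub("^[^*]*\\*", "", allele))
}

#' Read a supertype map from a two-column TSV
#'
#' The map assigns two-field class I alleles to one of the twelve HLA class
#' I supertypes (A01, A01A03, A01A24, A02, A03, A24, B07, B08, B27, B44,
#' B58, B62). The file has columns `allele` and `supertype`; `#` comment
#' lines are allowed. Alleles are normalized on read. The package ships an
#' editable map seeded from the Sidney-style functional classification at
#' `system.file("extdata", "supertype_map.tsv", package = "hlabench")`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `allele` and `supertype`.
#' @seealso [default_supertype_map()], [assign_supertype()]
#' @export
read_supertype_map <- function(path) {
  map <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("allele", "supertype")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("supertype map is missing column(s): ",
                         paste(miss, collapse = ", "))
  map$allele <- hla_normalize(map$allele)
  dup <- duplicated(map$allele)
  if (any(dup)) stop("duplicated allele in supertype map: ", map$allele[dup][1])
  tibble::as_tibble(map[need])
}

#' Bundled supertype map
#'
#' @return The supertype map shipped with the package, as a tibble.
#' @export
default_supertype_map <- function() {
  read_supertype_map(system.file("extdata", "supertype_map.tsv",
                                 package = "hlabench"))
}

#' Assign class I alleles to supertypes
#'
#' Lookup is total: class I alleles absent from the map return
#' `"unclassified"`. Class II alleles are a domain error because supertypes
#' are defined only for the peptide-binding pockets of class I molecules.
#'
#' @param allele Character vector of class I allele names (any dialect).
#' @param map A supertype map tibble (see [read_supertype_map()]).
#' @return Character vector of supertype labels or `"unclassified"`.
#' @examples
#' m <- tibble::tibble(allele = "B*44:02", supertype = "B44")
#' assign_supertype(c("B44:02", "B07:02"), m)
#' @export
assign_supertype <- function(allele, map) {
  a <- hla_normalize(allele)
  cls <- hla_class(hla_gene(a))
  if (any(cls != "I", na.rm = TRUE)) {
    stop("supertypes are defined for class I alleles only; got '",
         allele[which(cls != "I")[1]], "'")
  }
  out <- map$supertype[match(a, map$allele)]
  out[is.na(out) & !is.na(a)] <- "unclassified"
  out
}
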
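#' Default genetic-interaction sign map
#'
#' Maps BioGRID experimental-system labels to edge signs: alleviating
#' interactions ("Synthetic Rescue", "Positive Genetic") to +1 and aggravating
#' ones ("Synthetic Lethality", "Negative Genetic") to -1. Matching is
#' case-insensitive; any label absent from the map is ignored.
#'
#' @return named integer vector (label -> sign)
#' @export
default_gi_sign_map <- function() {
  c("synthetic rescue" = 1L, "positive genetic" = 1L,
    "synthetic lethality" = -1L, "negative genetic" = -1L)
}

#' Build a signed network from typed interaction records
#'
#' Applies a sign map to interaction-type labels and assembles a simple signed
#' network. Records whose label is not in the map are ignored; self-pairs are
#' dropped; unordered pairs supported by both a positive and a negative record
#' ("ambiguous" interactions) are removed entirely, mirroring the standard
#' curation step for genetic-interaction datasets.
#'
#' @param records data.frame with columns `gene_a`, `gene_b`, `type` (or any
#'   three columns in that order)
#' @param sign_map named vector mapping type labels to +1/-1 (case-insensitive
#'   on names); see [default_gi_sign_map()]
#' @return list with `network` (a [signed_network]) and `report`, a list of
#'   counts: `n_records`, `n_unmapped`, `n_self`, `n_ambiguous_pairs`,
#'   `n_edges`
#' @export
from_interaction_records <- function(records, sign_map = default_gi_sign_map()) {
  if (length(sign_map) == 0L) stop("sign_map must not be empty")
  if (any(!sign_map %in% c(-1L, 1L))) stop("sign_map values must be +1 or -1")
  names(sign_map) <- tolower(names(sign_map))
  if (ncol(records) < 3L) stop("records need 3 columns: gene_a, gene_b, type")
  a <- as.character(records[[1L]])
  b <- as.character(records[[2L]])
  type <- tolower(trimws(as.character(records[[3L]])))
  n_records <- length(a)
  mapped <- type %in% names(sign_map)
  n_unmapped <- sum(!mapped)
  a <- a[mapped]; b <- b[mapped]
  sign <- unname(sign_map[type[mapped]])
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; sign <- sign[!self]
  key <- edge_key(a, b)
  nsign <- vapply(split(sign, key), function(x) length(unique(x)), integer(1))
  ambiguous <- names(nsign)[nsign > 1L]
  keep <- !(key %in% ambiguous)
  df <- data.frame(from = a[keep], to = b[keep], sign = sign[keep],
                   stringsAsFactors = FALSE)
  net <- signed_network(df)
  list(network = net,
       report = list(n_records = n_records,
                     n_unmapped = n_unmapped,
                     n_self = n_self,
                     n_ambiguous_pairs = length(ambiguous),
                     n_edges = nrow(net$edges)))
}

#' Read a BioGRID-style tab-delimited file into interaction records
#'
#' Accepts any tab-delimited file with configurable 1-based column indices for
#' the two interactors and the experimental-system label. Defaults follow the
#' BioGRID TAB 2.0 layout: systematic names in columns 6/7 and experimental
#' system in column 12. An optional organism filter keeps only rows whose
#' organism columns both equal `taxon` (TAB 2.0 stores organism IDs in columns
#' 16/17); the default applies no filter since column layouts differ across
#' releases.
#'
#' @param path file path
#' @param col_a,col_b,col_type 1-based column indices for interactor A,
#'   interactor B and the interaction-type label
#' @param taxon optional organism identifier to filter on (character)
#' @param organism_cols 1-based indices of the two organism columns, used only
#'   when `taxon` is given
#' @param header does the file start with a header row (default TRUE)
#' @return data.frame with columns `gene_a`, `gene_b`, `type`, suitable for
#'   [from_interaction_records()]
#' @export
read_biogrid_records <- function(path, col_a = 6L, col_b = 7L, col_type = 12L,
                                 taxon = NULL, organism_cols = c(16L, 17L),
                                 header = TRUE) {
  tab <- utils::read.delim(path, header = header, comment.char = "#",
                           colClasses = "character", check.names = FALSE,
                           quote = "", stringsAsFactors = FALSE)
  need <- max(col_a, col_b, col_type,
              if (!is.null(taxon)) organism_cols else 0L)
  if (ncol(tab) < need) {
    stop("file has ", ncol(tab), " columns but column index ", need,
         " was requested")
  }
  if (!is.null(taxon)) {
    keep <- tab[[organism_cols[1L]]] == as.character(taxon) &
      tab[[organism_cols[2L]]] == as.character(taxon)
    tab <- tab[keep, , drop = FALSE]
  }
  data.frame(gene_a = tab[[col_a]], gene_b = tab[[col_b]],
             type = tab[[col_type]], stringsAsFactors = FALSE)
}

#' Build a genetic-interaction network from a BioGRID-style file
#'
#' Convenience wrapper: [read_biogrid_records()] followed by
#' [from_interaction_records()].
#'
#' @inheritParams read_biogrid_records
#' @param sign_map named vector mapping experimental-system labels to signs
#' @return list with `network` and `report` (see [from_interaction_records()])
#' @export
build_gin <- function(path, sign_map = default_gi_sign_map(),
                      col_a = 6L, col_b = 7L, col_type = 12L,
                      taxon = NULL, organism_cols = c(16L, 17L),
                      header = TRUE) {
  rec <- read_biogrid_records(path, col_a = col_a, col_b = col_b,
                              col_type = col_type, taxon = taxon,
                              organism_cols = organism_cols, header = header)
  from_interaction_records(rec, sign_map)
}
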
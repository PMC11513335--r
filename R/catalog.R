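FLUIDS <- c("P", "U", "BA", "BC")
PLATFORMS <- c("nt-ms", "t-ms", "Lipidyzer", "NMR", "PTRMS", "ICR", "chem.")
SUPER_PATHWAYS <- c("amino acids", "carbohydrates", "cofactors and vitamins",
                    "energy", "lipids", "nucleotides", "peptides",
                    "xenobiotics")

#' Platform-qualified metabolite identifier
#'
#' Metabolites measured on several platforms or in several fluids keep one
#' time course per (fluid, platform); identifiers therefore qualify the
#' compound name with a fluid tag (P: plasma, U: urine, BA: breath air,
#' BC: breath condensate) and a platform tag.
#'
#' @param display_name compound name as reported by the platform.
#' @param fluid one of \code{P, U, BA, BC}.
#' @param platform one of \code{nt-ms, t-ms, Lipidyzer, NMR, PTRMS, ICR, chem.}
#' @export
make_uid <- function(display_name, fluid, platform) {
  stopifnot(all(fluid %in% FLUIDS), all(platform %in% PLATFORMS))
  sprintf("%s [%s; %s]", display_name, fluid, platform)
}

#' Metabolite catalog
#'
#' @param display_name compound names.
#' @param fluid,platform tags, recycled (see [make_uid()]).
#' @param super_pathway one of the eight metabolite classes.
#' @param sub_pathway free-text pathway annotation.
#' @param kegg,hmdb,chebi,pubchem optional external accessions.
#' @param synonyms pipe-separated synonym strings.
#' @return data.frame of class \code{metabolite_catalog} with a unique
#'   \code{uid} per row.
#' @export
metabolite_catalog <- function(display_name, fluid = "P", platform = "nt-ms",
                               super_pathway = "xenobiotics",
                               sub_pathway = NA_character_,
                               kegg = NA_character_, hmdb = NA_character_,
                               chebi = NA_character_,
                               pubchem = NA_character_, synonyms = "") {
  n <- length(display_name)
  cat <- data.frame(
    uid = make_uid(display_name, rep_len(fluid, n), rep_len(platform, n)),
    display_name = display_name,
    fluid = rep_len(fluid, n), platform = rep_len(platform, n),
    super_pathway = rep_len(super_pathway, n),
    sub_pathway = rep_len(sub_pathway, n),
    kegg = rep_len(kegg, n), hmdb = rep_len(hmdb, n),
    chebi = rep_len(chebi, n), pubchem = rep_len(pubchem, n),
    synonyms = rep_len(synonyms, n),
    stringsAsFactors = FALSE)
  validate_catalog(cat)
}

validate_catalog <- function(cat) {
  need <- c("uid", "display_name", "fluid", "platform", "super_pathway",
            "sub_pathway", "kegg", "hmdb", "chebi", "pubchem", "synonyms")
  miss <- setdiff(need, names(cat))
  if (length(miss) > 0)
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cat$uid))
    stop("duplicate uid in catalog: ", cat$uid[duplicated(cat$uid)][1])
  if (!all(cat$fluid %in% FLUIDS))
    stop("unknown fluid tag: ", setdiff(cat$fluid, FLUIDS)[1])
  if (!all(cat$platform %in% PLATFORMS))
    stop("unknown platform tag: ", setdiff(cat$platform, PLATFORMS)[1])
  class(cat) <- c("metabolite_catalog", "data.frame")
  cat
}

#' Read / write a metabolite catalog (TSV)
#'
#' @param path file path.
#' @param cat a catalog.
#' @rdname catalog_io
#' @export
read_catalog <- function(path) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  cat$synonyms[is.na(cat$synonyms)] <- ""
  validate_catalog(cat)
}

#' @rdname catalog_io
#' @export
write_catalog <- function(cat, path) {
  utils::write.table(cat, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
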
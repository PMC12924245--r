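# Rule-based functional categorization of phage genes, morphology
# classification, and inducibility assessment. The decision layer is a
# keyword lexicon over product strings (shipped as an editable TSV,
# priority = file order, most specific keyword first), so the module works
# on any GenBank/GFF3 annotation without a protein database.

FUNCTIONAL_CATEGORIES <- c(
  "integrase", "transposase", "terminase_large", "terminase_small",
  "portal", "head", "neck", "tail", "tail_sheath", "tape_measure",
  "baseplate", "lysis", "nucleic_acid_metabolism", "regulation",
  "hypothetical", "other")

#' Load the functional keyword lexicon
#'
#' @param path Path to a two-column TSV (`keyword`, `category`); defaults to
#'   the lexicon shipped with the package. Row order is priority order.
#' @return Data.frame with `keyword` (lower case) and `category`.
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "functional_lexicon.tsv",
                        package = "phagewatch")
  }
  lex <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("keyword", "category") %in% names(lex))) {
    stop("load_lexicon: lexicon needs 'keyword' and 'category' columns")
  }
  bad <- !lex$category %in% FUNCTIONAL_CATEGORIES
  if (any(bad)) stop("load_lexicon: unknown category ",
                     paste(unique(lex$category[bad]), collapse = ", "))
  lex$keyword <- tolower(lex$keyword)
  lex
}

#' Map a product string to a functional category
#'
#' Case-insensitive keyword lookup in lexicon order (most specific keyword
#' first, e.g. "tail sheath" before "tail"). An empty product or
#' "hypothetical protein" maps to `hypothetical`; anything unmatched maps
#' to `other`. The mapping is total and deterministic.
#'
#' @param product Character vector of product descriptions.
#' @param lexicon Lexicon data.frame from [load_lexicon()].
#' @return Character vector of categories, same length as `product`.
#' @export
map_functional_category <- function(product, lexicon = load_lexicon()) {
  p <- tolower(trimws(as.character(product)))
  p[is.na(p)] <- ""
  out <- rep("other", length(p))
  out[p == "" | p == "hypothetical protein"] <- "hypothetical"
  todo <- which(out == "other")
  for (i in seq_len(nrow(lexicon))) {
    if (!length(todo)) break
    hit <- grepl(lexicon$keyword[i], p[todo], fixed = TRUE)
    out[todo[hit]] <- lexicon$category[i]
    todo <- todo[!hit]
  }
  out
}

#' Classify prophage morphology from categorized genes
#'
#' A tail sheath protein indicates a contractile-tailed myovirus; a tail
#' tape measure protein without a tail sheath protein indicates a
#' siphovirus; otherwise the morphology is undetermined.
#'
#' @param categories Character vector of functional categories.
#' @return `"myovirus"`, `"siphovirus"` or `"undetermined"`.
#' @export
classify_morphology <- function(categories) {
  if ("tail_sheath" %in% categories) return("myovirus")
  if ("tape_measure" %in% categories) return("siphovirus")
  "undetermined"
}

INDUCIBILITY_BLOCKS <- c("integrase", "structural", "terminase", "lysis",
                         "nucleic_acid_metabolism")

#' Assess prophage inducibility from gene-block presence
#'
#' A prophage is judged intact when all five gene blocks needed to re-enter
#' the lytic cycle are present: (i) an integrase or transposase; (ii) the
#' structural set — portal, head, and a tail component (tail, tail sheath
#' or tape measure; neck optional); (iii) a terminase subunit (large or
#' small); (iv) a lysis gene (endolysin, spanin, holin); (v) a nucleic acid
#' metabolism gene (polymerase, helicase, ligase, ...). Integrase position
#' is reported but presence alone is required.
#'
#' @param categories Character vector of functional categories for the
#'   prophage's genes.
#' @return List with `status` (`"intact"`/`"defective"`), `missing_blocks`
#'   (character vector) and `rationale` (text).
#' @export
assess_inducibility <- function(categories) {
  has <- function(x) any(categories %in% x)
  present <- c(
    integrase = has(c("integrase", "transposase")),
    structural = has("portal") && has("head") &&
      has(c("tail", "tail_sheath", "tape_measure")),
    terminase = has(c("terminase_large", "terminase_small")),
    lysis = has("lysis"),
    nucleic_acid_metabolism = has("nucleic_acid_metabolism"))
  missing <- names(present)[!present]
  status <- if (length(missing) == 0) "intact" else "defective"
  rationale <- if (status == "intact") {
    "all five gene blocks required for lytic reproduction are present"
  } else {
    paste("missing gene block(s):", paste(missing, collapse = ", "))
  }
  list(status = status, missing_blocks = missing, rationale = rationale)
}

#' Annotate a prophage region: categories, morphology, inducibility
#'
#' @param region One-row data.frame with `start`/`end` (and optionally
#'   `region_id`).
#' @param features Feature data.frame for the host genome (internal
#'   coordinates); genes overlapping the region are used.
#' @param lexicon Lexicon from [load_lexicon()].
#' @return List of class `prophage_record`: `region`, `genes` (with a
#'   `category` column), `morphology`, `inducibility`.
#' @export
annotate_prophage <- function(region, features, lexicon = load_lexicon()) {
  genes <- features[features$start < region$end & features$end > region$start, ,
                    drop = FALSE]
  genes$category <- map_functional_category(genes$product, lexicon)
  rec <- list(region = region, genes = genes,
              morphology = classify_morphology(genes$category),
              inducibility = assess_inducibility(genes$category))
  class(rec) <- "prophage_record"
  rec
}

#' @export
print.prophage_record <- function(x, ...) {
  id <- if ("region_id" %in% names(x$region)) x$region$region_id else "region"
  cat(sprintf("<prophage_record> %s [%d, %d): %d genes, %s, %s\n",
              id, x$region$start, x$region$end, nrow(x$genes),
              x$morphology, x$inducibility$status))
  invisible(x)
}
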
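# Tabular data model: identification records, reference taxonomy, sample
# metadata.  Records live in a long data frame, one row per suggestion,
# keyed by (tool, sample, replicate); a row with position 0 and category
# no_id encodes an attempt that returned no identification.

.RECORD_COLS <- c("tool", "sample", "replicate", "position",
                  "suggested_name", "category")

#' Construct a validated set of identification records
#'
#' @param df Data frame with columns \code{tool}, \code{sample},
#'   \code{replicate}, \code{position}, \code{suggested_name},
#'   \code{category}; one row per ranked suggestion.  \code{position = 0}
#'   with \code{category = "no_id"} encodes an attempt with no suggestions.
#' @return The data frame, validated and classed \code{"taxid_records"}.
#' @details Validation enforces the closed category vocabulary
#'   (case-insensitively), uniqueness of (tool, sample, replicate, position),
#'   and that each record's positions are consecutive from 1.
#' @export
as_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.RECORD_COLS, names(df))
  if (length(missing_cols))
    stop("records are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[.RECORD_COLS]
  df$tool <- as.character(df$tool)
  df$sample <- as.character(df$sample)
  df$replicate <- as.integer(df$replicate)
  df$position <- as.integer(df$position)
  df$suggested_name <- as.character(df$suggested_name)
  df$suggested_name[is.na(df$suggested_name)] <- ""
  df$category <- validate_categories(df$category, context = seq_len(nrow(df)))

  noid <- df$position == 0L
  if (any(noid & df$category != "no_id"))
    stop("position 0 is reserved for no_id rows (row ",
         which(noid & df$category != "no_id")[1L], ")", call. = FALSE)
  if (any(!noid & df$category == "no_id"))
    stop("no_id rows must have position 0 (row ",
         which(!noid & df$category == "no_id")[1L], ")", call. = FALSE)

  key4 <- paste(df$tool, df$sample, df$replicate, df$position, sep = "\r")
  if (anyDuplicated(key4))
    stop("duplicate (tool, sample, replicate, position): row ",
         which(duplicated(key4))[1L], call. = FALSE)

  key3 <- paste(df$tool, df$sample, df$replicate, sep = "\r")
  for (k in unique(key3[noid]))
    if (any(key3 == k & !noid))
      stop("record ", gsub("\r", "/", k),
           " mixes a no_id row with suggestions", call. = FALSE)
  pos_ok <- vapply(split(df$position[!noid], key3[!noid]),
                   function(p) identical(sort(p), seq_along(p)),
                   logical(1))
  if (!all(pos_ok))
    stop("suggestion positions not consecutive from 1 for record(s): ",
         paste(gsub("\r", "/", names(pos_ok)[!pos_ok]), collapse = "; "),
         call. = FALSE)

  df <- df[order(df$tool, df$sample, df$replicate, df$position), ]
  rownames(df) <- NULL
  class(df) <- c("taxid_records", "data.frame")
  df
}

#' Read identification records from a delimited file
#'
#' @param path Path to a CSV (or TSV) file with header columns
#'   \code{tool,sample,replicate,position,suggested_name,category}.
#' @param sep Field separator; \code{","} by default.
#' @return A validated \code{"taxid_records"} data frame
#'   (see \code{\link{as_records}}).
#' @export
read_records <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  as_records(df)
}

#' Write identification records to CSV
#'
#' Round-trip safe: \code{read_records(write_records(x))} reproduces
#' \code{x} exactly.
#'
#' @param records A \code{"taxid_records"} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_records <- function(records, path) {
  records <- as_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a reference taxonomy
#'
#' @param path CSV file with columns \code{species}, \code{genus},
#'   \code{family}.
#' @return A validated taxonomy data frame, one row per species.  Exact
#'   duplicate rows are collapsed; the same species listed with conflicting
#'   genus or family is an error.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  as_taxonomy(df)
}

#' @rdname read_taxonomy
#' @param df Data frame with columns \code{species}, \code{genus},
#'   \code{family}.
#' @export
as_taxonomy <- function(df) {
  need <- c("species", "genus", "family")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("taxonomy is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- unique(as.data.frame(df, stringsAsFactors = FALSE)[need])
  if (any(!nzchar(df$family))) stop("taxonomy has empty family", call. = FALSE)
  dup <- duplicated(df$species)
  if (any(dup))
    stop("species listed with conflicting genus/family: ",
         paste(unique(df$species[dup]), collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Read per-sample metadata
#'
#' @param path CSV file with columns \code{sample}, \code{species},
#'   \code{plant_part} (flower/fruit/leaf/plant) and \code{plant_type}
#'   (herb/monocot/woody).
#' @return Validated metadata data frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as_sample_metadata(utils::read.csv(path, colClasses = "character",
                                     fileEncoding = "UTF-8"))
}

#' @rdname read_sample_metadata
#' @param df Data frame with the metadata columns above.
#' @export
as_sample_metadata <- function(df) {
  need <- c("sample", "species", "plant_part", "plant_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  if (anyDuplicated(df$sample))
    stop("duplicate sample id in metadata: ",
         df$sample[duplicated(df$sample)][1L], call. = FALSE)
  df$plant_part <- check_vocab(tolower(df$plant_part),
                               c("flower", "fruit", "leaf", "plant"),
                               "plant_part")
  df$plant_type <- check_vocab(tolower(df$plant_type),
                               c("herb", "monocot", "woody"),
                               "plant_type")
  rownames(df) <- NULL
  df
}

check_vocab <- function(x, allowed, what) {
  bad <- !(x %in% allowed)
  if (any(bad))
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(sQuote(unique(x[bad])), collapse = ", ")),
         call. = FALSE)
  x
}

# Look up the (genus, family) of suggested names in the taxonomy.  Returns a
# data frame with columns species, genus, family; NA genus/family where a
# name is not a listed species.
resolve_names <- function(names, taxonomy) {
  i <- match(names, taxonomy$species)
  data.frame(species = names,
             genus = taxonomy$genus[i],
             family = taxonomy$family[i],
             stringsAsFactors = FALSE)
}

#' Objective taxonomic match classification
#'
#' Compares a suggested species against the reference determination through
#' the taxonomy: equal binomials give \code{species_correct}, equal genera
#' \code{genus_correct}, equal families \code{family_correct}, anything else
#' \code{unknown}.  The subjective categories (very close, similar genus,
#' good try, misleading, ...) are expert annotations and are never produced
#' here; annotation may override the objective fallback in the input data.
#'
#' @param suggested,reference Character vectors of species binomials
#'   (recycled to a common length).
#' @param taxonomy Taxonomy data frame (see \code{\link{read_taxonomy}}).
#' @return Character vector of objective category labels.
#' @examples
#' tax <- as_taxonomy(data.frame(
#'   species = c("Quercus robur", "Quercus cerris", "Fagus sylvatica"),
#'   genus   = c("Quercus", "Quercus", "Fagus"),
#'   family  = c("Fagaceae", "Fagaceae", "Fagaceae")))
#' classify_exact("Quercus cerris", "Quercus robur", tax)  # genus_correct
#' @export
classify_exact <- function(suggested, reference, taxonomy) {
  n <- max(length(suggested), length(reference))
  suggested <- rep_len(as.character(suggested), n)
  reference <- rep_len(as.character(reference), n)
  s <- resolve_names(suggested, taxonomy)
  r <- resolve_names(reference, taxonomy)
  if (any(is.na(s$family)))
    stop("suggested taxon not in taxonomy: ",
         paste(unique(suggested[is.na(s$family)]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(r$family)))
    stop("reference taxon not in taxonomy: ",
         paste(unique(reference[is.na(r$family)]), collapse = ", "),
         call. = FALSE)
  out <- rep("unknown", n)
  out[s$family == r$family] <- "family_correct"
  out[s$genus == r$genus] <- "genus_correct"
  out[suggested == reference] <- "species_correct"
  out
}
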
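# Name matching across observation, survey and trait tables, species trait
# means, plot-level community-weighted means and trait-tagged occurrences.

#' Normalize a species name to its primary binomial
#'
#' Truncates a raw name to its first two whitespace-delimited tokens and
#' lowercases them, discarding authority strings, hybrid markers and
#' infraspecific epithets. Single-token names cannot form a binomial and are
#' returned as \code{NA} (unmatched) rather than padded or guessed.
#'
#' @param rawName character vector of raw species names.
#' @return character vector of normalized binomials (\code{NA} where the
#'   input has fewer than two tokens).
#' @examples
#' normalizeName("Quercus robur L.")   # "quercus robur"
#' normalizeName("QUERCUS   ROBUR")    # "quercus robur"
#' is.na(normalizeName("Poa"))         # TRUE
#' @export
normalizeName <- function(rawName) {
  if (length(rawName) == 0L) return(character(0))
  if (any(is.na(rawName)) || any(!nzchar(trimws(rawName)))) {
    stop("empty or missing species name", call. = FALSE)
  }
  toks <- strsplit(trimws(tolower(rawName)), "\\s+")
  vapply(toks, function(t) {
    if (length(t) < 2L) NA_character_ else paste(t[1:2], collapse = " ")
  }, character(1))
}

#' Species-level trait means from a measurement table
#'
#' Computes the arithmetic mean measurement per (normalized binomial, trait)
#' and retains measurement counts. Rows with non-finite values or
#' un-normalizable (single-token) names are rejected with a warning.
#'
#' @param db data.frame with columns \code{species}, \code{trait},
#'   \code{value} (as produced by [subsetTraitDB()]).
#' @return data.frame with columns \code{binomial}, \code{trait},
#'   \code{mean}, \code{count}.
#' @export
speciesMeans <- function(db) {
  stopifnot(all(c("species", "trait", "value") %in% names(db)))
  if (nrow(db) == 0L) stop("trait measurement table is empty", call. = FALSE)
  bad <- !is.finite(db$value)
  if (any(bad)) {
    warning(sum(bad), " non-finite measurement(s) rejected", call. = FALSE)
    db <- db[!bad, , drop = FALSE]
  }
  bin <- normalizeName(db$species)
  if (anyNA(bin)) {
    warning(sum(is.na(bin)), " measurement(s) with non-binomial names rejected",
            call. = FALSE)
    db <- db[!is.na(bin), , drop = FALSE]
    bin <- bin[!is.na(bin)]
  }
  key <- paste(bin, db$trait, sep = "\r")
  mu <- tapply(db$value, key, mean)
  n <- tapply(db$value, key, length)
  parts <- strsplit(names(mu), "\r", fixed = TRUE)
  out <- data.frame(binomial = vapply(parts, `[`, "", 1L),
                    trait = vapply(parts, `[`, "", 2L),
                    mean = as.numeric(mu), count = as.integer(n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$trait, out$binomial), ]
}

.traitMeanLookup <- function(means, traitName) {
  m <- means[means$trait == traitName, ]
  if (nrow(m) == 0L) {
    stop("trait '", traitName, "' absent from species means", call. = FALSE)
  }
  setNames(m$mean, m$binomial)
}

#' Plot-level community-weighted mean traits
#'
#' For each plot, CWM = sum(cover_s * mean_s) / sum(cover_s) over species
#' matched in the trait means table. Unmatched species are dropped and the
#' remaining covers renormalized (\code{renormalize = FALSE} instead treats
#' unmatched cover as zero-trait mass in the denominator). Plots with zero
#' matched cover are dropped. The matched-cover fraction is reported per
#' plot so both behaviours remain comparable.
#'
#' @param surveys data.frame with columns \code{plotId}, \code{x}, \code{y},
#'   \code{binomial}, \code{cover}.
#' @param means species trait means from [speciesMeans()].
#' @param traitName trait to compute.
#' @param renormalize drop unmatched species and renormalize covers
#'   (default TRUE).
#' @return data.frame with columns \code{plotId}, \code{x}, \code{y},
#'   \code{trait}, \code{cwm}, \code{matchedCover}.
#' @export
plotCWM <- function(surveys, means, traitName, renormalize = TRUE) {
  stopifnot(all(c("plotId", "x", "y", "binomial", "cover") %in% names(surveys)))
  lut <- .traitMeanLookup(means, traitName)
  bin <- normalizeName(surveys$binomial)
  tv <- lut[bin]
  matched <- !is.na(tv)
  sp <- split(seq_len(nrow(surveys)), surveys$plotId)
  rows <- lapply(sp, function(idx) {
    w <- surveys$cover[idx]
    m <- matched[idx]
    wm <- sum(w[m])
    if (wm <= 0) return(NULL)
    denom <- if (renormalize) wm else sum(w)
    data.frame(plotId = surveys$plotId[idx[1]],
               x = surveys$x[idx[1]], y = surveys$y[idx[1]],
               trait = traitName,
               cwm = sum(w[m] * tv[idx][m]) / denom,
               matchedCover = wm / sum(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no plot retained any matched cover for trait '", traitName, "'",
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Tag occurrence records with species mean trait values
#'
#' Records whose normalized binomial is absent from the trait means are
#' dropped; retained records carry the species mean. The number of dropped
#' records is attached as attribute \code{"nDropped"} and summarized by
#' [matchReport()].
#'
#' @param occ data.frame with columns \code{recordId}, \code{x}, \code{y},
#'   \code{binomial}.
#' @param means species trait means from [speciesMeans()].
#' @param traitName trait to tag with.
#' @return data.frame with columns \code{recordId}, \code{x}, \code{y},
#'   \code{binomial}, \code{trait}, \code{value}; attribute \code{nDropped}.
#' @export
tagOccurrences <- function(occ, means, traitName) {
  stopifnot(all(c("recordId", "x", "y", "binomial") %in% names(occ)))
  lut <- .traitMeanLookup(means, traitName)
  bin <- normalizeName(occ$binomial)
  tv <- lut[bin]
  keep <- !is.na(tv)
  out <- data.frame(recordId = occ$recordId[keep], x = occ$x[keep],
                    y = occ$y[keep], binomial = bin[keep],
                    trait = rep(traitName, sum(keep)),
                    value = as.numeric(tv[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "nDropped") <- sum(!keep)
  out
}

#' Retention bookkeeping for a matching run
#'
#' @param surveys raw survey table; @param occ raw occurrence table;
#' @param means species trait means; @param traitName trait considered.
#' @return list with retained/dropped record and species counts, suitable
#'   for JSON serialization.
#' @export
matchReport <- function(surveys, occ, means, traitName) {
  lut <- .traitMeanLookup(means, traitName)
  sbin <- normalizeName(surveys$binomial)
  obin <- normalizeName(occ$binomial)
  list(trait = traitName,
       surveyRecords = nrow(surveys),
       surveyRecordsMatched = sum(sbin %in% names(lut)),
       surveySpecies = length(unique(sbin)),
       surveySpeciesMatched = length(unique(sbin[sbin %in% names(lut)])),
       occurrenceRecords = nrow(occ),
       occurrenceRecordsMatched = sum(obin %in% names(lut)),
       occurrenceSpecies = length(unique(obin)),
       occurrenceSpeciesMatched = length(unique(obin[obin %in% names(lut)])))
}
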
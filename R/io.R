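## On-disk library schema (header names are fixed):
##   fragment_id, pocket_id, smiles, n_heavy, affinity_value, affinity_kind
## affinity_kind is one of kd_M, kd_nM, kd_uM, dg_kcal_mol; Kd values are
## converted to signed free energies at parse time.

.AFFINITY_KINDS <- c(kd_M = 1, kd_nM = 1e-9, kd_uM = 1e-6)

#' Read a fragment library table
#'
#' Reads a delimited text table (comma or tab, sniffed from the header
#' line) into a [PocketLibrary-class]. Affinities given as dissociation
#' constants are converted to signed binding free energies
#' (\eqn{\Delta G = RT \ln K_d}); `dg_kcal_mol` rows are taken as-is.
#' Heavy-atom counts may be given explicitly, derived from a SMILES
#' column, or both — in which case they must agree.
#'
#' @param path Path to the table. Required columns: `fragment_id`,
#'   `pocket_id`, `affinity_value`, `affinity_kind`, and at least one of
#'   `smiles` / `n_heavy`.
#' @param params A [ThermoParams-class] for Kd conversion.
#' @param targetId Target identifier attached to the library.
#' @return A [PocketLibrary-class], rows in file order.
#' @seealso [writeLibrary()], [readSdfFragments()]
#' @export
readLibrary <- function(path, params = thermoParams(), targetId = "target") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = c("NA", ""))
  required <- c("fragment_id", "pocket_id", "affinity_value", "affinity_kind")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("library schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!any(c("smiles", "n_heavy") %in% names(df)))
    stop("library schema error: need a 'smiles' or 'n_heavy' column",
         call. = FALSE)
  if (!"smiles" %in% names(df)) df$smiles <- NA_character_
  if (!"n_heavy" %in% names(df)) df$n_heavy <- NA_integer_

  bad <- which(is.na(df$smiles) & is.na(df$n_heavy))
  if (length(bad))
    stop(sprintf("row(s) %s carry neither 'smiles' nor 'n_heavy'",
                 paste(bad, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(unique(df$affinity_kind),
                     c(names(.AFFINITY_KINDS), "dg_kcal_mol"))
  if (length(unknown))
    stop(sprintf("unknown affinity_kind value(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)

  hasSmiles <- !is.na(df$smiles)
  if (any(hasSmiles)) {
    derived <- vapply(which(hasSmiles), function(i) {
      tryCatch(heavyAtomCount(df$smiles[i])[[1]],
               error = function(e)
                 stop(sprintf("row %d (fragment '%s'): %s", i,
                              df$fragment_id[i], conditionMessage(e)),
                      call. = FALSE))
    }, integer(1))
    explicit <- df$n_heavy[hasSmiles]
    clash <- !is.na(explicit) & explicit != derived
    if (any(clash)) {
      i <- which(hasSmiles)[clash][1]
      stop(sprintf("row %d (fragment '%s'): n_heavy %d disagrees with SMILES-derived count %d",
                   i, df$fragment_id[i], df$n_heavy[i],
                   derived[clash][1]), call. = FALSE)
    }
    df$n_heavy[hasSmiles] <- derived
  }

  isKd <- df$affinity_kind %in% names(.AFFINITY_KINDS)
  if (any(isKd & (is.na(df$affinity_value) | df$affinity_value <= 0)))
    stop("Kd affinities must be positive", call. = FALSE)
  deltaG <- df$affinity_value
  if (any(isKd)) {
    molar <- df$affinity_value[isKd] *
      .AFFINITY_KINDS[df$affinity_kind[isKd]]
    deltaG[isKd] <- deltaGFromKd(molar, params)
  }
  PocketLibrary(data.frame(
    fragment_id = as.character(df$fragment_id),
    pocket_id = as.character(df$pocket_id),
    delta_g = deltaG, n_heavy = as.integer(df$n_heavy),
    smiles = as.character(df$smiles), stringsAsFactors = FALSE
  ), targetId = targetId)
}

#' Write a fragment library in the canonical table schema
#'
#' Free energies are written as `dg_kcal_mol` rows at full precision, so
#' [readLibrary()] round-trips the library.
#'
#' @param library A [PocketLibrary-class].
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
writeLibrary <- function(library, path) {
  stopifnot(is(library, "PocketLibrary"))
  df <- fragments(library)
  out <- data.frame(
    fragment_id = df$fragment_id, pocket_id = df$pocket_id,
    smiles = df$smiles, n_heavy = df$n_heavy,
    affinity_value = sprintf("%.15g", df$delta_g),
    affinity_kind = "dg_kcal_mol", stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read fragments from an SDF file
#'
#' Reads MDL V2000 records via ChemmineR. Each record must carry a pocket
#' property and exactly one affinity property named after the canonical
#' affinity kinds (`kd_M`, `kd_nM`, `kd_uM` or `dg_kcal_mol`). Heavy
#' atoms are counted from the connection table. Records missing the
#' required properties are skipped with a summarising warning; the rest
#' are still loaded.
#'
#' @param path Path to an SDF file.
#' @param pocketField Name of the data field holding the pocket id.
#' @param params A [ThermoParams-class] for Kd conversion.
#' @return A data.frame in the fragment schema (`fragment_id`,
#'   `pocket_id`, `delta_g`, `n_heavy`, `smiles = NA`), suitable for
#'   [PocketLibrary()].
#' @export
readSdfFragments <- function(path, pocketField = "pocket",
                             params = thermoParams()) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  hasRecords <- any(nzchar(trimws(readLines(path, warn = FALSE))))
  if (!hasRecords || !length(sdf <- suppressWarnings(ChemmineR::read.SDFset(path)))) {
    warning("empty SDF: no fragments read")
    return(data.frame(fragment_id = character(0), pocket_id = character(0),
                      delta_g = numeric(0), n_heavy = integer(0),
                      smiles = character(0), stringsAsFactors = FALSE))
  }
  ids <- ChemmineR::sdfid(sdf)
  blocks <- ChemmineR::datablock(sdf)
  counts <- ChemmineR::atomcount(sdf)
  rows <- vector("list", length(sdf))
  skipped <- character(0)
  for (k in seq_along(sdf)) {
    props <- blocks[[k]]
    kinds <- intersect(names(props), c(names(.AFFINITY_KINDS), "dg_kcal_mol"))
    if (!pocketField %in% names(props) || length(kinds) != 1) {
      skipped <- c(skipped, ids[k])
      next
    }
    value <- suppressWarnings(as.numeric(props[[kinds]]))
    if (is.na(value)) { skipped <- c(skipped, ids[k]); next }
    deltaG <- if (kinds == "dg_kcal_mol") value
              else deltaGFromKd(value * .AFFINITY_KINDS[[kinds]], params)
    ct <- counts[[k]]
    rows[[k]] <- data.frame(
      fragment_id = ids[k], pocket_id = as.character(props[[pocketField]]),
      delta_g = deltaG,
      n_heavy = as.integer(sum(ct[names(ct) != "H"])),
      smiles = NA_character_, stringsAsFactors = FALSE
    )
  }
  if (length(skipped))
    warning(sprintf("skipped %d SDF record(s) lacking pocket/affinity properties: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(fragment_id = character(0), pocket_id = character(0),
                      delta_g = numeric(0), n_heavy = integer(0),
                      smiles = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a screen report
#'
#' CSV: one row per accepted combination (pocket columns, `le_t_app` at
#' six decimal places, rescued ids). JSON: the full result — accepted
#' combinations at full precision, the classification map, per-class
#' counts and a config echo — re-readable with [readReport()].
#'
#' @param result A [ScreenResult-class].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(result, path, format = c("csv", "json")) {
  stopifnot(is(result, "ScreenResult"))
  format <- match.arg(format)
  if (format == "csv") {
    df <- result@accepted
    df$le_t_app <- sprintf("%.6f", df$le_t_app)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    cfg <- result@config
    payload <- list(
      target_id = result@targetId,
      config = list(cutoff = cfg@cutoff, mode = cfg@mode,
                    # Inf is not valid JSON; stringify and parse back
                    max_combinations_reported =
                      format(cfg@maxCombinationsReported),
                    allow_nonbinders = cfg@allowNonbinders,
                    tolerance = cfg@tolerance, seed = cfg@seed),
      counts = as.list(result@counts),
      classification = as.list(result@classification),
      stats = result@stats,
      accepted = result@accepted
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read a JSON screen report back
#'
#' @param path Path to a JSON report written by [writeReport()].
#' @return A [ScreenResult-class] equal to the one written.
#' @export
readReport <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- new("ScreenConfig", cutoff = p$config$cutoff, mode = p$config$mode,
             maxCombinationsReported =
               as.numeric(p$config$max_combinations_reported),
             allowNonbinders = p$config$allow_nonbinders,
             tolerance = p$config$tolerance,
             seed = as.integer(p$config$seed))
  acceptedDf <- as.data.frame(p$accepted, stringsAsFactors = FALSE)
  if (!nrow(acceptedDf) && length(p$accepted))
    acceptedDf <- as.data.frame(lapply(p$accepted, unlist),
                                stringsAsFactors = FALSE)
  new("ScreenResult", accepted = acceptedDf,
      classification = unlist(p$classification),
      counts = stats::setNames(as.integer(unlist(p$counts)), names(p$counts)),
      config = cfg, targetId = p$target_id,
      stats = p$stats)
}
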
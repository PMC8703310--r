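#' Load the built-in metabolite registry
#'
#' Returns the package's transcription of the phantom measurement table:
#' for each of 17 phosphorus metabolite entries (15 measured in phantoms plus
#' the two literature-only entries, membrane phospholipids and GPE), the
#' constituent \eqn{^{31}}P signals with multiplicity, J-coupling, assigned
#' coupling-partner nucleus and the chemical-shift variants (phantom pH 7.0,
#' phantom pH 7.5, in vivo, literature basis, fitting basis).
#'
#' All shifts are in ppm relative to phosphocreatine at 0 ppm; J-couplings in
#' Hz. Signals with a fitting-basis shift (`shift_basisp`) are eligible for
#' basis construction; the two ADP resonances are deliberately excluded
#' because they are fully overlapped by the much stronger alpha- and gamma-ATP
#' resonances in vivo.
#'
#' @return An object of class `phos_registry`: a list with elements
#'   `entries` (named list of `phos_metabolite` entries), `components`
#'   (data frame of all signals) and `version`.
#' @examples
#' reg <- load_registry()
#' reg$entries$Pi$components$shift_ph70   # 4.78
#' @export
load_registry <- function() {
  comps <- .phos_component_table()
  ents <- .phos_entry_table()
  entries <- lapply(seq_len(nrow(ents)), function(i) {
    e <- as.list(ents[i, ])
    e$components <- comps[comps$abbrev == e$abbrev, , drop = FALSE]
    rownames(e$components) <- NULL
    class(e) <- "phos_metabolite"
    e
  })
  names(entries) <- ents$abbrev
  reg <- list(entries = entries, components = comps, version = "1.0")
  class(reg) <- "phos_registry"
  validate_registry(reg)
  reg
}

#' @export
print.phos_registry <- function(x, ...) {
  cat(sprintf("<phos_registry v%s> %d entries, %d signals (%d basis-eligible)\n",
              x$version, length(x$entries), nrow(x$components),
              sum(!is.na(x$components$shift_basisp))))
  invisible(x)
}

# Internal consistency checks run on load and after import.
validate_registry <- function(reg) {
  comps <- reg$components
  stopifnot(length(reg$entries) == 17L)
  mult <- comps$multiplicity
  bad <- mult != "s" & (is.na(comps$j_hz) | comps$j_hz <= 0 |
                          comps$partner == "none")
  if (any(bad))
    stop("registry: multiplet signal without positive J or coupling partner: ",
         paste(comps$label[bad], collapse = ", "))
  # fitting-basis shifts must sit close to a measured or in vivo shift
  has_b <- !is.na(comps$shift_basisp)
  for (i in which(has_b)) {
    ref <- c(comps$shift_ph70[i], comps$invivo[i])
    ref <- ref[!is.na(ref)]
    if (length(ref) && min(abs(comps$shift_basisp[i] - ref)) > 1.0)
      stop("registry: basis shift of ", comps$label[i],
           " further than 1 ppm from any reference shift")
  }
  if (any(comps$abbrev[has_b] == "ADP"))
    stop("registry: ADP signals must not be basis-eligible")
  pcr <- comps[comps$abbrev == "PCr", ]
  stopifnot(nrow(pcr) == 1L, pcr$multiplicity == "s",
            pcr$shift_ph70 == 0, pcr$shift_ph75 == 0)
  n_by <- table(comps$abbrev)
  stopifnot(n_by[["ATP"]] == 3L, n_by[["ADP"]] == 2L,
            n_by[["DPG23"]] == 2L, n_by[["UDPG"]] == 2L)
  invisible(reg)
}

#' Select the signals that enter the fitting basis
#'
#' The default selection contains every signal with a fitting-basis chemical
#' shift: 20 signals from 16 entries, with the three ATP resonances
#' contributed as three independent basis members and both ADP resonances
#' excluded. Members are ordered by descending ppm, ties broken
#' alphabetically by label, so output columns are reproducible.
#'
#' @param registry A `phos_registry`.
#' @param include Optional character vector of entry abbreviations or signal
#'   labels to restrict to.
#' @param exclude Optional character vector of entry abbreviations or signal
#'   labels to drop.
#' @return A data frame of signal rows (one per basis member).
#' @examples
#' sigs <- basis_signals(load_registry())
#' nrow(sigs)                      # 20
#' any(sigs$abbrev == "ADP")       # FALSE
#' @export
basis_signals <- function(registry, include = NULL, exclude = NULL) {
  stopifnot(inherits(registry, "phos_registry"))
  comps <- registry$components
  sel <- comps[!is.na(comps$shift_basisp), , drop = FALSE]
  resolve <- function(nms) {
    known <- unique(c(comps$abbrev, comps$label))
    bad <- setdiff(nms, known)
    if (length(bad))
      stop("unknown metabolite or signal name: ", paste(bad, collapse = ", "))
    sel$abbrev %in% nms | sel$label %in% nms
  }
  if (!is.null(include)) sel <- sel[resolve(include), , drop = FALSE]
  if (!is.null(exclude)) sel <- sel[!resolve(exclude), , drop = FALSE]
  sel <- sel[order(-sel$shift_basisp, sel$label), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Look up one chemical-shift variant of a signal
#'
#' @param component A single signal row (as returned by [basis_signals()] or
#'   found in an entry's `components`), or a `phos_registry` together with a
#'   signal `label`.
#' @param variant One of `"ph70"`, `"ph75"`, `"invivo"`, `"basisp"`,
#'   `"deelchand"`.
#' @param label Signal label when `component` is a registry.
#' @return The stored shift in ppm. A missing variant (for instance G1P at
#'   pH 7.5, where the signal is overlaid by inorganic phosphate) raises an
#'   error rather than silently substituting another column.
#' @examples
#' reg <- load_registry()
#' shift_variant(reg, "basisp", label = "PCr")   # 0
#' @export
shift_variant <- function(component, variant = c("ph70", "ph75", "invivo",
                                                 "basisp", "deelchand"),
                          label = NULL) {
  variant <- match.arg(variant)
  if (inherits(component, "phos_registry")) {
    stopifnot(!is.null(label))
    comps <- component$components
    row <- comps[comps$label == label, , drop = FALSE]
    if (nrow(row) != 1L) stop("unknown signal label: ", label)
    component <- row
  }
  col <- switch(variant, ph70 = "shift_ph70", ph75 = "shift_ph75",
                invivo = "invivo", basisp = "shift_basisp",
                deelchand = "shift_deelchand")
  val <- component[[col]]
  if (length(val) != 1L || is.na(val))
    stop("shift variant '", variant, "' is not available for signal '",
         component$label, "'")
  as.numeric(val)
}

# multiplicity actually realized under a decoupling state
effective_multiplicity <- function(component, decoupled) {
  m <- component$multiplicity
  if (!decoupled) return(m)
  if (!is.na(component$dec_mult)) return(component$dec_mult)
  if (identical(component$partner, "proton")) return("s")
  m
}

#' Export / import the registry
#'
#' The registry round-trips through two plain-text formats: a tab-separated
#' table of signals (full double precision) and a versioned JSON document.
#' Reloading reproduces every numeric field bit-exactly.
#'
#' @param registry A `phos_registry`.
#' @param path Output/input file path.
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   `phos_registry`.
#' @export
write_registry_tsv <- function(registry, path) {
  stopifnot(inherits(registry, "phos_registry"))
  comps <- registry$components
  num <- vapply(comps, is.numeric, logical(1))
  out <- comps
  for (j in which(num)) out[[j]] <- ifelse(is.na(comps[[j]]), "NA",
                                           sprintf("%.17g", comps[[j]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_registry_tsv
#' @export
read_registry_tsv <- function(path) {
  comps <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, na.strings = "NA",
                             colClasses = "character")
  ref <- .phos_component_table()
  for (nm in names(ref)) {
    if (is.numeric(ref[[nm]])) comps[[nm]] <- as.numeric(comps[[nm]])
  }
  reg <- load_registry()
  reg$components <- comps[, names(ref)]
  for (ab in names(reg$entries)) {
    reg$entries[[ab]]$components <-
      comps[comps$abbrev == ab, names(ref), drop = FALSE]
    rownames(reg$entries[[ab]]$components) <- NULL
  }
  validate_registry(reg)
  reg
}

#' @rdname write_registry_tsv
#' @export
write_registry_json <- function(registry, path) {
  stopifnot(inherits(registry, "phos_registry"))
  doc <- list(schema = "phosfit-registry", schema_version = 1L,
              version = registry$version,
              entries = .phos_entry_table(),
              components = registry$components)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry_tsv
#' @export
read_registry_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "phosfit-registry"))
    stop("not a phosfit registry document: ", path)
  ref <- .phos_component_table()
  comps <- as.data.frame(doc$components, stringsAsFactors = FALSE)
  for (nm in names(ref)) {
    comps[[nm]] <- if (is.numeric(ref[[nm]])) as.numeric(comps[[nm]])
                   else as.character(comps[[nm]])
  }
  reg <- load_registry()
  reg$components <- comps[, names(ref)]
  for (ab in names(reg$entries)) {
    reg$entries[[ab]]$components <-
      comps[comps$abbrev == ab, names(ref), drop = FALSE]
    rownames(reg$entries[[ab]]$components) <- NULL
  }
  validate_registry(reg)
  reg
}
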
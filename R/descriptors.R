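#' Construct a descriptor matrix with per-descriptor metadata
#'
#' A descriptor matrix couples observation rows (plants for classification,
#' accessions for functional diversity) with a metadata table declaring
#' each descriptor's class (`numeric`, `ordinal`, `nominal`) and type
#' (`phenomic`, `classical`), plus declared level orders for ordinals.
#'
#' @param data Data.frame of descriptor values (rows = observation units).
#' @param meta Data.frame with columns `name`, `dclass`, `dtype`, `organ`;
#'   one row per descriptor column of `data`.
#' @param accession Accession id per row.
#' @param species Species label per row.
#' @param levels Named list of level vectors for ordinal/nominal
#'   descriptors (order defines ordinal ranks).
#' @return A `descriptor_matrix` object.
#' @export
descriptor_matrix <- function(data, meta, accession, species, levels = list()) {
  stopifnot(is.data.frame(data), is.data.frame(meta),
            all(c("name", "dclass", "dtype") %in% names(meta)),
            nrow(meta) == ncol(data), !anyDuplicated(meta$name),
            length(accession) == nrow(data), length(species) == nrow(data),
            all(meta$dclass %in% c("numeric", "ordinal", "nominal")),
            all(meta$dtype %in% c("phenomic", "classical")))
  names(data) <- meta$name
  full_na <- vapply(data, function(col) all(is.na(col)), logical(1))
  if (any(full_na)) stop("fully-missing descriptor column(s): ",
                         paste(meta$name[full_na], collapse = ", "))
  for (nm in meta$name[meta$dclass != "numeric"]) {
    if (is.null(levels[[nm]])) {
      if (meta$dclass[meta$name == nm] == "ordinal")
        stop("ordinal descriptor '", nm, "' has no declared levels")
      levels[[nm]] <- sort(unique(stats::na.omit(data[[nm]])))
    }
    bad <- setdiff(unique(stats::na.omit(data[[nm]])), levels[[nm]])
    if (length(bad)) stop("undeclared level(s) in '", nm, "': ",
                          paste(bad, collapse = ", "))
  }
  num <- meta$name[meta$dclass == "numeric"]
  nonfin <- vapply(data[num], function(col) any(!is.finite(col) & !is.na(col)),
                   logical(1))
  if (any(nonfin)) stop("non-finite numeric values in: ",
                        paste(num[nonfin], collapse = ", "))
  structure(list(data = data, meta = meta,
                 accession = as.character(accession),
                 species = as.character(species), levels = levels),
            class = "descriptor_matrix")
}

#' Assemble phenomic, classical or combined descriptor matrices
#'
#' Joins plant- or accession-level phenomic rows with the classical table
#' on accession id. Combined mode takes the column union of both sets;
#' rows lacking either part are dropped (with a message reporting the
#' count). Rows are returned sorted by accession so assembly is
#' order-independent.
#'
#' @param phenomic A `descriptor_matrix` of phenomic descriptors (or NULL
#'   for `mode = "classical"`).
#' @param classical A `descriptor_matrix` of classical descriptors, one row
#'   per accession (or NULL for `mode = "phenomic"`).
#' @param species_map Data.frame with `accession`, `species` columns
#'   covering every accession in the inputs.
#' @param mode One of `"phenomic"`, `"classical"`, `"combined"`.
#' @return A `descriptor_matrix`.
#' @export
assemble_descriptors <- function(phenomic, classical, species_map,
                                 mode = c("combined", "phenomic", "classical")) {
  mode <- match.arg(mode)
  lookup <- stats::setNames(species_map$species, species_map$accession)
  check_known <- function(m) {
    unk <- setdiff(unique(m$accession), names(lookup))
    if (length(unk)) stop("accession(s) not in species map: ",
                          paste(unk, collapse = ", "))
  }
  if (mode == "phenomic") {
    check_known(phenomic)
    return(sort_dm(phenomic))
  }
  if (mode == "classical") {
    check_known(classical)
    return(sort_dm(classical))
  }
  check_known(phenomic); check_known(classical)
  if (length(intersect(phenomic$meta$name, classical$meta$name)))
    stop("descriptor name collision between phenomic and classical sets")
  keep <- phenomic$accession %in% classical$accession
  dropped <- sum(!keep) +
    sum(!classical$accession %in% phenomic$accession)
  if (dropped > 0)
    message(dropped, " row(s) dropped: accession present in only one set")
  ph <- phenomic$data[keep, , drop = FALSE]
  acc <- phenomic$accession[keep]
  cl <- classical$data[match(acc, classical$accession), , drop = FALSE]
  dm <- descriptor_matrix(cbind(ph, cl),
                          rbind(phenomic$meta, classical$meta),
                          accession = acc, species = unname(lookup[acc]),
                          levels = c(phenomic$levels, classical$levels))
  sort_dm(dm)
}

sort_dm <- function(dm) {
  o <- order(dm$accession)
  dm$data <- dm$data[o, , drop = FALSE]
  rownames(dm$data) <- NULL
  dm$accession <- dm$accession[o]
  dm$species <- dm$species[o]
  dm
}

#' Aggregate a plant-level descriptor matrix to accession level
#'
#' Numeric descriptors take the within-accession mean; ordinal and nominal
#' descriptors take the mode (ties broken lexicographically).
#'
#' @param dm A `descriptor_matrix` with replicate rows per accession.
#' @return A `descriptor_matrix` with one row per accession.
#' @export
aggregate_to_accession <- function(dm) {
  accs <- sort(unique(dm$accession))
  agg <- lapply(seq_len(ncol(dm$data)), function(j) {
    col <- dm$data[[j]]
    if (dm$meta$dclass[j] == "numeric") {
      vapply(accs, function(a) mean(col[dm$accession == a], na.rm = TRUE),
             numeric(1))
    } else {
      vapply(accs, function(a) {
        tab <- sort(table(col[dm$accession == a]), decreasing = TRUE)
        top <- names(tab)[tab == max(tab)]
        sort(top)[1]
      }, character(1))
    }
  })
  names(agg) <- dm$meta$name
  sp <- dm$species[match(accs, dm$accession)]
  descriptor_matrix(as.data.frame(agg, stringsAsFactors = FALSE), dm$meta,
                    accession = accs, species = sp, levels = dm$levels)
}

#' Encode a descriptor matrix numerically for random-forest input
#'
#' Ordinals become their declared rank integers (0-based), nominals become
#' one-hot indicator columns, numerics pass through. The reverse map links
#' every encoded column back to its parent descriptor so minimal depths can
#' be aggregated to parent level (parent depth = min over child columns).
#' Missing numeric values are imputed with the column mean and categorical
#' ones with the mode, provided missingness is at most 10% per column.
#'
#' @param dm A `descriptor_matrix`.
#' @return List: `x` (numeric matrix), `parent` (named chr vector, encoded
#'   column -> parent descriptor), `accession`, `species`.
#' @export
encode_for_rf <- function(dm) {
  cols <- list(); parent <- character(0)
  for (j in seq_len(ncol(dm$data))) {
    nm <- dm$meta$name[j]
    col <- dm$data[[j]]
    if (mean(is.na(col)) > 0.10)
      stop("descriptor '", nm, "' exceeds 10% missingness")
    if (dm$meta$dclass[j] == "numeric") {
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      cols[[nm]] <- col
      parent[nm] <- nm
    } else if (dm$meta$dclass[j] == "ordinal") {
      r <- match(col, dm$levels[[nm]]) - 1
      if (any(is.na(r) & !is.na(col)))
        stop("undeclared ordinal level in '", nm, "'")
      r[is.na(r)] <- as.numeric(names(which.max(table(r))))
      cols[[nm]] <- r
      parent[nm] <- nm
    } else {
      lv <- dm$levels[[nm]]
      col[is.na(col)] <- names(which.max(table(col)))
      for (l in lv) {
        cn <- paste0(nm, "=", l)
        cols[[cn]] <- as.numeric(col == l)
        parent[cn] <- nm
      }
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  list(x = x, parent = parent, accession = dm$accession, species = dm$species)
}
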
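# Readers and writers for external formats: multi-model PDB ensembles,
# the line-oriented restraint dialect, scattering curves, tabulated
# distance distributions and population tables.

#' Read a multi-model PDB file as an ensemble
#'
#' Models are read through bio3d and returned in file order. Populations
#' are uniform unless a sidecar population table is given. All models
#' must share one atom layout.
#'
#' @param path PDB file path.
#' @param populations Optional numeric vector or path to a population
#'   table (see [read_population_table()]).
#' @return An [ensemble()].
#' @export
read_ensemble_pdb <- function(path, populations = NULL) {
  layout_bad <- FALSE
  pdb <- withCallingHandlers(
    tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
             error = function(e)
               stop("malformed PDB or inconsistent atom layout in '",
                    path, "': ", conditionMessage(e))),
    warning = function(w) {
      if (grepl("multiple|cartesian", conditionMessage(w)))
        layout_bad <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (layout_bad)
    stop("inconsistent atom layout across models in '", path, "'")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- ncol(xyz) / 3
  n_models <- nrow(xyz)
  if (n_atoms != nrow(pdb$atom))
    stop("inconsistent atom layout across models in '", path, "'")
  coords <- array(0, dim = c(n_atoms, 3, n_models))
  for (i in seq_len(n_models))
    coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(chain = pdb$atom$chain, resno = pdb$atom$resno,
                      elety = pdb$atom$elety, resid = pdb$atom$resid,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  if (is.character(populations))
    populations <- read_population_table(populations, n_models)
  ensemble(coords, atoms = atoms, populations = populations)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits standard `MODEL`/`ATOM`/`ENDMDL` records (coordinates at PDB
#' precision, 3 decimals). Re-readable by [read_ensemble_pdb()].
#'
#' @param e An [ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(e, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- e$atoms
  name4 <- vapply(at$elety, function(nm) {
    if (nchar(nm) >= 4) substr(nm, 1, 4)
    else sprintf(" %-3s", nm)
  }, "")
  for (m in seq_len(n_conformers(e))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    x <- matrix(e$coords[, , m], ncol = 3)
    lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     seq_len(nrow(at)), name4, substr(at$resid, 1, 3),
                     substr(at$chain, 1, 1), at$resno,
                     x[, 1], x[, 2], x[, 3], 1.00, 0.00)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a population table
#'
#' Tab-separated, two columns: 1-based model index (matching the PDB
#' `MODEL` records) and population.
#'
#' @param path File path.
#' @param n_models Expected model count (checked when given).
#' @return Numeric population vector in model order.
#' @export
read_population_table <- function(path, n_models = NULL) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("model", "population"))
  if (any(!is.finite(tab$model)) || any(!is.finite(tab$population)))
    stop("non-numeric population table entries")
  if (anyDuplicated(tab$model)) stop("duplicate model indices")
  if (any(tab$population < 0)) stop("negative populations")
  if (is.null(n_models)) n_models <- max(tab$model)
  p <- numeric(n_models)
  p[tab$model] <- tab$population
  p
}

#' Write a population table
#' @param p Population vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(p, path) {
  utils::write.table(data.frame(model = seq_along(p), population = p),
                     path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a restraint/configuration file
#'
#' Line-oriented dialect; `#` starts a comment. Keywords:
#' \describe{
#'   \item{`RIGID <body-id> <pdb-file> <chains>`}{declare a rigid body
#'     (chains comma-separated).}
#'   \item{`DDR <site-a> <site-b> <mean A> <sigma A> [role]`}{Gaussian
#'     distance restraint; sites as `CHAIN.RESNO`; role defaults to
#'     `reference`.}
#'   \item{`LINKER <peptide|rna> <anchor-a> <anchor-b|-> <length>`}{
#'     flexible linker declaration; anchors as `body:name`; `-` for a
#'     free end.}
#'   \item{`XLINK <site-a> <site-b> <max A>`}{crosslink restraint.}
#'   \item{`PARAM <name> <value>`}{parameter override (`t_max`, `p_thr`,
#'     `f_x`, `rna_max`, `peptide_max`, `clash_cutoff`, `upper_default`,
#'     `sigma_label`).}
#' }
#'
#' @param path File path.
#' @return List with `restraints` (list of [distance_restraint()]),
#'   `linkers` (list of [linker_spec()]), `rigid` (data frame of body
#'   declarations) and `params` (defaults applied).
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  params <- list(t_max = 10000, p_thr = 0.5, f_x = 1, rna_max = 7,
                 peptide_max = 3.8, clash_cutoff = 2.0,
                 upper_default = 180, sigma_label = 3)
  restraints <- list(); linkers <- list()
  rigid <- data.frame(id = character(), file = character(),
                      chains = character(), stringsAsFactors = FALSE)
  seen_pairs <- character()
  num <- function(x, ln) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("line ", ln, ": non-numeric field '", x, "'")
    v
  }
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "") next
    kw <- toupper(tok[1])
    if (kw == "PARAM") {
      if (length(tok) != 3) stop("line ", ln, ": PARAM needs name and value")
      params[[tolower(tok[2])]] <- num(tok[3], ln)
    } else if (kw == "RIGID") {
      if (length(tok) < 3) stop("line ", ln, ": RIGID needs id and file")
      rigid <- rbind(rigid, data.frame(
        id = tok[2], file = tok[3],
        chains = if (length(tok) >= 4) tok[4] else "",
        stringsAsFactors = FALSE))
    } else if (kw == "DDR") {
      if (length(tok) < 5) stop("line ", ln, ": DDR needs 4+ fields")
      key <- paste(sort(tok[2:3]), collapse = "|")
      if (key %in% seen_pairs)
        stop("line ", ln, ": duplicate DDR for site pair ", tok[2], " ",
             tok[3])
      seen_pairs <- c(seen_pairs, key)
      role <- if (length(tok) >= 6) tok[6] else "reference"
      restraints[[length(restraints) + 1]] <-
        distance_restraint(tok[2], tok[3], mean = num(tok[4], ln),
                           sigma = num(tok[5], ln), role = role,
                           upper_default = params$upper_default)
    } else if (kw == "XLINK") {
      if (length(tok) != 4) stop("line ", ln, ": XLINK needs 3 fields")
      restraints[[length(restraints) + 1]] <-
        distance_restraint(tok[2], tok[3], lower = 1,
                           upper = num(tok[4], ln), role = "crosslink")
    } else if (kw == "LINKER") {
      if (length(tok) != 5) stop("line ", ln, ": LINKER needs 4 fields")
      type <- tolower(tok[2])
      if (!type %in% c("peptide", "rna"))
        stop("line ", ln, ": unknown linker type '", tok[2], "'")
      linkers[[length(linkers) + 1]] <-
        linker_spec(type, length = num(tok[5], ln), anchor_a = tok[3],
                    anchor_b = if (tok[4] == "-") NULL else tok[4])
    } else {
      stop("line ", ln, ": unknown keyword '", tok[1], "'")
    }
  }
  list(restraints = restraints, linkers = linkers, rigid = rigid,
       params = params)
}

#' Read a small-angle scattering curve
#'
#' Whitespace-delimited 3-column text (`q` in 1/Angstrom, intensity,
#' uncertainty); `#` starts a comment. Rows are sorted by `q`.
#'
#' @param path File path.
#' @return A [sas_curve()].
#' @export
read_sas_curve <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("q", "I", "sigma"))
  if (any(!is.finite(as.matrix(tab)))) stop("non-numeric curve entries")
  tab <- tab[order(tab$q), ]
  if (anyDuplicated(tab$q)) stop("duplicate q values")
  if (any(tab$sigma <= 0)) stop("sigma must be > 0")
  sas_curve(tab$q, tab$I, tab$sigma)
}

#' Write a scattering curve
#' @param curve A [sas_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sas_curve <- function(curve, path) {
  utils::write.table(data.frame(curve$q, curve$intensity, curve$sigma),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a tabulated distance distribution
#'
#' Whitespace-delimited 2-column text (`r` in Angstrom, density). The
#' distribution is renormalized to unit area, with a warning when the
#' input area deviates by more than 1 percent.
#'
#' @param path File path.
#' @return A [distance_distribution()].
#' @export
read_distribution <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("r", "p"))
  if (any(!is.finite(as.matrix(tab)))) stop("non-numeric entries")
  tab <- tab[order(tab$r), ]
  if (any(diff(tab$r) <= 0)) stop("non-monotonic distance axis")
  if (any(tab$p < 0)) stop("negative density values")
  a <- trapz_area(tab$r, tab$p)
  if (abs(a - 1) > 0.01)
    warning("distribution area ", signif(a, 4), " renormalized to 1")
  distance_distribution(tab$r, tab$p)
}

#' Write a tabulated distance distribution
#' @param d A [distance_distribution()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(d, path) {
  utils::write.table(data.frame(d$r, d$p), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load rigid bodies declared in a restraint file
#'
#' Reads each `RIGID` PDB (first model), selects the declared chains,
#' and attaches sites for every `CHAIN.RESNO` tag that appears in the
#' restraints: tags of reference-role restraints become reference sites
#' (exactly 3 per body required), remaining tags become auxiliary sites.
#' Site positions are the residue's CA (or P/C1') atom.
#'
#' @param config A [read_restraints()] result.
#' @param dir Directory against which relative PDB paths are resolved.
#' @param site_uncertainty Positional uncertainty assigned to all sites,
#'   Angstrom.
#' @return List of [rigid_body()] objects.
#' @export
load_bodies <- function(config, dir = ".", site_uncertainty = 0) {
  if (nrow(config$rigid) == 0) stop("no RIGID declarations")
  ref_tags <- unique(unlist(lapply(
    Filter(function(r) r$role == "reference", config$restraints),
    function(r) c(r$site_a, r$site_b))))
  all_tags <- unique(unlist(lapply(config$restraints,
                                   function(r) c(r$site_a, r$site_b))))
  lapply(seq_len(nrow(config$rigid)), function(k) {
    row <- config$rigid[k, ]
    f <- if (file.exists(row$file)) row$file else file.path(dir, row$file)
    e <- read_ensemble_pdb(f)
    chains <- strsplit(row$chains, ",")[[1]]
    sel <- if (length(chains)) which(e$atoms$chain %in% chains)
           else seq_len(nrow(e$atoms))
    atoms <- e$atoms[sel, , drop = FALSE]
    xyz <- e$coords[sel, , 1, drop = TRUE]
    tags <- paste0(atoms$chain, ".", atoms$resno)
    trace <- atoms$elety %in% c("CA", "P", "C1'", "C1*")
    site_at <- function(tag) {
      hit <- which(tags == tag & trace)
      if (length(hit) == 0) return(NULL)
      label_site(atoms$chain[hit[1]], atoms$resno[hit[1]], xyz[hit[1], ],
                 tag = tag, uncertainty = site_uncertainty)
    }
    refs <- Filter(Negate(is.null), lapply(ref_tags, site_at))
    auxs <- Filter(Negate(is.null),
                   lapply(setdiff(all_tags, ref_tags), site_at))
    if (length(refs) != 3)
      stop("body '", row$id, "' has ", length(refs),
           " reference sites; exactly 3 required")
    anchors <- list(n = xyz[1, ], c = xyz[nrow(xyz), ])
    rigid_body(xyz, atoms, ref_sites = refs, aux_sites = auxs,
               anchors = anchors, id = row$id)
  })
}
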
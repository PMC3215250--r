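## Residue assignment strings come in several habits: "24", "24Trp",
## "W24", "Trp24", "24W".  All reduce to the residue number.
.parse_residue <- function(x) {
  m <- regmatches(x, regexpr("[0-9]+", x))
  if (!length(m)) return(NA_integer_)
  as.integer(m)
}

#' Read a peak list
#'
#' Supported dialects:
#' \describe{
#'   \item{generic_tsv}{two whitespace/tab-separated columns: residue,
#'     intensity; \code{#} starts a comment.}
#'   \item{sparky_like}{assignment string (e.g. \code{W24N-H}) followed
#'     by the intensity in the last numeric column.}
#'   \item{nmrview_table}{a header line naming the columns; residue
#'     number is taken from the first column, intensity from the column
#'     named \code{Intensity} (case-insensitive), otherwise the last
#'     column.}
#' }
#'
#' Unparseable lines are skipped with a line-numbered warning; a file
#' yielding zero rows is a hard error.
#'
#' @param path file path.
#' @param dialect one of \code{"generic_tsv"}, \code{"sparky_like"},
#'   \code{"nmrview_table"}.
#' @return named numeric vector: intensity keyed by residue number.
#' @export
read_peak_list <- function(path,
                           dialect = c("generic_tsv", "sparky_like",
                                       "nmrview_table")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  raw_n <- length(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty peak list: ", path)

  header <- NULL
  if (dialect == "nmrview_table") {
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  res <- numeric(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[\\s,\t]+", perl = TRUE)[[1]]
    parsed <- switch(dialect,
      generic_tsv = {
        if (length(tok) < 2) NULL
        else list(res = .parse_residue(tok[1]),
                  int = suppressWarnings(as.numeric(tok[2])))
      },
      sparky_like = {
        val <- suppressWarnings(as.numeric(tok))
        num <- which(is.finite(val))
        if (!length(num) || length(tok) < 2) NULL
        else list(res = .parse_residue(tok[1]),
                  int = val[num[length(num)]])
      },
      nmrview_table = {
        val <- suppressWarnings(as.numeric(tok))
        icol <- grep("^intensity$", header, ignore.case = TRUE)
        icol <- if (length(icol)) icol[1] else length(tok)
        if (length(tok) < icol) NULL
        else list(res = .parse_residue(tok[1]), int = val[icol])
      })
    if (is.null(parsed) || is.na(parsed$res) || !is.finite(parsed$int)) {
      warning("line ", lineno[i], ": unparseable, skipped")
      next
    }
    res[as.character(parsed$res)] <- parsed$int
  }
  if (!length(res)) stop("no peaks parsed from ", path)
  message(length(res), " peaks parsed from ", raw_n, " raw lines (",
          path, ")")
  res
}

#' Read a Bruker variable-delay (vd/vc) list as a CPMG schedule
#'
#' One numeric token per line; zero or a blank line marks the reference
#' spectrum.  In \code{frequency_hz} mode the values are taken as
#' nu_CPMG directly; in \code{loop_count} mode nu_CPMG = count / T_CPMG.
#'
#' @param path file path.
#' @param t_cpmg constant CPMG period, seconds.
#' @param mode \code{"frequency_hz"} or \code{"loop_count"}.
#' @param field a \code{\link{field_context}}.
#' @return a \code{\link{cpmg_schedule}}; spectra are numbered
#'   \code{sp1, sp2, ...} in file order.
#' @export
read_vd_list <- function(path, t_cpmg,
                         mode = c("frequency_hz", "loop_count"),
                         field = field_context(600)) {
  mode <- match.arg(mode)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!grepl("^#", lines)]
  vals <- suppressWarnings(as.numeric(lines))
  vals[lines == ""] <- 0
  if (any(is.na(vals))) stop("non-numeric entry in vd list: ", path)
  if (any(vals < 0)) stop("negative value in vd list: ", path)
  nu <- ifelse(vals == 0, NA_real_,
               if (mode == "frequency_hz") vals else vals / t_cpmg)
  cpmg_schedule(paste0("sp", seq_along(nu)), nu, t_cpmg, field)
}

#' Read a protein sequence
#'
#' Accepts a FASTA file, a plain one-letter string, or a PDB file
#' (SEQRES records if present, otherwise the ATOM records of the first
#' chain, preserving author residue numbering).
#'
#' @param source file path or plain sequence string.
#' @param type \code{"auto"}, \code{"fasta"}, \code{"string"} or
#'   \code{"pdb"}.
#' @return named character vector: one-letter amino acid codes keyed by
#'   residue number (1-based for FASTA/string, author numbering for
#'   PDB).
#' @export
read_sequence <- function(source, type = c("auto", "fasta", "string",
                                           "pdb")) {
  type <- match.arg(type)
  if (type == "auto") {
    type <- if (!file.exists(source)) "string"
            else if (grepl("\\.pdb$", source, ignore.case = TRUE)) "pdb"
            else "fasta"
  }
  aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  seq_chars <- switch(type,
    string = strsplit(toupper(gsub("\\s", "", source)), "")[[1]],
    fasta = {
      lines <- readLines(source, warn = FALSE)
      body <- lines[!grepl("^>", lines)]
      strsplit(toupper(gsub("\\s", "", paste(body, collapse = ""))),
               "")[[1]]
    },
    pdb = NULL)
  if (type != "pdb") {
    if (!length(seq_chars)) stop("empty sequence")
    return(stats::setNames(seq_chars, seq_along(seq_chars)))
  }
  lines <- readLines(source, warn = FALSE)
  seqres <- grep("^SEQRES", lines, value = TRUE)
  atoms <- grep("^ATOM", lines, value = TRUE)
  if (length(atoms)) {
    # author numbering from ATOM records of the first chain
    chain <- substr(atoms[1], 22, 22)
    atoms <- atoms[substr(atoms, 22, 22) == chain]
    resno <- as.integer(substr(atoms, 23, 26))
    resna <- trimws(substr(atoms, 18, 20))
    keep <- !duplicated(resno)
    out <- stats::setNames(unname(aa3to1[resna[keep]]),
                           resno[keep])
    return(out[!is.na(out)])
  }
  if (length(seqres)) {
    chain <- substr(seqres[1], 12, 12)
    seqres <- seqres[substr(seqres, 12, 12) == chain]
    toks <- unlist(lapply(seqres, function(l)
      strsplit(trimws(substr(l, 20, nchar(l))), "\\s+")[[1]]))
    out <- unname(aa3to1[toks])
    out <- out[!is.na(out)]
    return(stats::setNames(out, seq_along(out)))
  }
  stop("no sequence records found in ", source)
}

.fmt6 <- function(x) ifelse(is.na(x), "", signif(x, 6))

#' Write a results CSV
#'
#' One row per residue and model with all parameters, Monte Carlo
#' errors, chi-square and information-criterion scores, the selected
#' flag and R_ex.  Column order and 6-significant-figure formatting are
#' fixed so output is byte-identical across runs.
#'
#' @param selections list of \code{"cpmg_selection"} objects carrying
#'   their per-model fits (as produced by \code{\link{fit_models}}).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_results_csv <- function(selections, path) {
  if (inherits(selections, "cpmg_selection"))
    selections <- list(selections)
  if (!length(selections)) stop("no results to write")
  rows <- list()
  for (sel in selections) {
    fits <- attr(sel, "fits")
    if (is.null(fits)) fits <- list(sel$fit)
    for (f in fits) {
      e <- f$errors
      rows[[length(rows) + 1]] <- data.frame(
        residue = sel$residue, model = f$model,
        selected = as.integer(identical(f$model, sel$selected)),
        r20 = .fmt6(f$pars$r20[[1]]),
        r20_err = .fmt6(if (is.null(e)) NA else e$r20[[1]]),
        kex = .fmt6(if (f$model > 1) f$pars$kex else NA),
        kex_err = .fmt6(if (is.null(e) || f$model == 1) NA else e$kex),
        pb = .fmt6(if (f$model == 3) f$pars$pb else NA),
        pb_err = .fmt6(if (is.null(e) || f$model != 3) NA else e$pb),
        dw = .fmt6(if (f$model == 3) f$pars$dw else NA),
        dw_err = .fmt6(if (is.null(e) || f$model != 3) NA else e$dw),
        phi = .fmt6(if (f$model == 2) f$pars$phi else NA),
        rex = .fmt6(f$rex), chi2 = .fmt6(f$chi2),
        aic = .fmt6(f$aic), aicc = .fmt6(f$aicc))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$residue, out$model), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write dispersion profiles as CSV
#'
#' Columns: residue, field_MHz, nu_cpmg_Hz, r2eff, sigma.
#'
#' @param profiles list of \code{\link{dispersion_profile}} objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "dispersion_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    d <- p$data
    data.frame(residue = p$residue, field_MHz = d$field_mhz,
               nu_cpmg_Hz = d$nu_cpmg, r2eff = signif(d$r2eff, 10),
               sigma = signif(p$sigma[as.character(d$field_mhz)], 10))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read dispersion profiles from CSV
#'
#' Inverse of \code{\link{write_profiles_csv}}: expects columns residue,
#' field_MHz, nu_cpmg_Hz, r2eff, sigma.
#'
#' @param path CSV file.
#' @param ref_frequency_mhz reference field delta-omega values are
#'   quoted at; defaults to each profile's own field.
#' @return named list of \code{\link{dispersion_profile}} objects.
#' @export
read_profiles_csv <- function(path, ref_frequency_mhz = NULL) {
  d <- utils::read.csv(path)
  need <- c("residue", "field_MHz", "nu_cpmg_Hz", "r2eff", "sigma")
  if (!all(need %in% names(d)))
    stop("profiles CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (res in unique(d$residue)) {
    dr <- d[d$residue == res, ]
    keys <- as.character(unique(dr$field_MHz))
    sigma <- vapply(keys, function(f)
      dr$sigma[dr$field_MHz == as.numeric(f)][1], 0)
    ref_ok <- !is.null(ref_frequency_mhz) && !is.na(ref_frequency_mhz)
    fields <- stats::setNames(lapply(keys, function(f)
      field_context(as.numeric(f),
                    if (ref_ok) ref_frequency_mhz
                    else as.numeric(f))), keys)
    out[[as.character(res)]] <- dispersion_profile(
      residue = res,
      data = data.frame(field_mhz = dr$field_MHz,
                        nu_cpmg = dr$nu_cpmg_Hz, r2eff = dr$r2eff),
      sigma = sigma, fields = fields)
  }
  out
}

#' Write a PyMOL macro color-coding a structure
#'
#' Residues without data are colored black; analyzed residues are
#' colored by selected model id (fixed palette) or, for continuous
#' values (kex, Rex), on a yellow-to-red ramp over the observed range
#' with cartoon/line width growing proportionally to the value.
#'
#' @param values named numeric vector (or, in model mode, integer model
#'   ids) keyed by residue number.
#' @param mode \code{"model"}, \code{"kex"} or \code{"rex"}.
#' @param path output .pml file.
#' @param known_residues optional residue numbers present in the
#'   structure; values for absent residues are skipped with a warning.
#' @return the path, invisibly.
#' @export
write_pymol_macro <- function(values, mode = c("model", "kex", "rex"),
                              path, known_residues = NULL) {
  mode <- match.arg(mode)
  resno <- as.integer(names(values))
  if (!is.null(known_residues)) {
    absent <- !(resno %in% known_residues)
    if (any(absent)) {
      warning("residue(s) absent from structure skipped: ",
              paste(resno[absent], collapse = ", "))
      values <- values[!absent]; resno <- resno[!absent]
    }
  }
  lines <- c("bg_color white", "hide everything", "show cartoon",
             "color black")
  if (!length(values)) {
    warning("no residues to color; macro contains only the black default")
  } else if (mode == "model") {
    palette <- c("1" = "blue", "2" = "green", "3" = "red")
    for (i in seq_along(values))
      lines <- c(lines, sprintf("color %s, resi %d",
                                palette[[as.character(values[i])]],
                                resno[i]))
  } else {
    rng <- range(values)
    span <- if (diff(rng) > 0) diff(rng) else 1
    for (i in seq_along(values)) {
      t <- (values[i] - rng[1]) / span     # 0 = yellow, 1 = red
      lines <- c(lines,
        sprintf("set_color ramp_%d, [1.0, %.3f, 0.0]", resno[i], 1 - t),
        sprintf("color ramp_%d, resi %d", resno[i], resno[i]),
        sprintf("set cartoon_tube_radius, %.3f, resi %d",
                0.3 + 0.9 * t, resno[i]),
        sprintf("set line_width, %.1f, resi %d", 1 + 4 * t, resno[i]))
    }
    lines <- c(lines, "set cartoon_tube, 1")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a project configuration file
#'
#' A YAML description of a full analysis: schedule files per field, peak
#' lists per spectrum, optional sequence source, output directory,
#' selection criterion, Monte Carlo settings and the model set to fit.
#'
#' @param path YAML file.
#' @return validated config list with defaults filled in
#'   (\code{criterion} AICc, \code{mc_sims} 500, \code{models} 1:3).
#' @export
read_project_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read project configs")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$fields) || !length(cfg$fields))
    stop("config must name at least one field with a schedule")
  for (f in cfg$fields)
    if (is.null(f$schedule) || is.null(f$peak_lists))
      stop("every field needs 'schedule' and 'peak_lists' entries")
  cfg$criterion <- cfg$criterion %||% "AICc"
  cfg$mc_sims <- cfg$mc_sims %||% 500
  cfg$models <- cfg$models %||% 1:3
  cfg$output_dir <- cfg$output_dir %||% "."
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
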
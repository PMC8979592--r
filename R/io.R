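## Plain-text I/O: trajectory frames as commented CSV, molecule templates and
## scenarios as JSON, coordinates as XYZ / minimal PDB, meshes as OFF.

#' Write trajectory frames to CSV with header metadata
#'
#' Header lines (prefixed `#`) record the scenario kind, model parameters and
#' seed; the body is the frame table.
#'
#' @param traj An `rd_trajectory`. @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "rd_trajectory"))
  sc <- traj$scenario
  p <- sc$params
  hdr <- c(
    paste0("# scenario: ", sc$kind),
    paste0("# seed: ", if (is.null(traj$meta$seed)) "NA" else traj$meta$seed),
    paste0("# dt_us: ", traj$meta$dt_us),
    paste0("# params: ",
           paste(sprintf("%s=%g", c("KD_CC", "KD_AC", "dG_coop", "dG_strain",
                                    "h", "rho_AP", "k_AP_CLA", "k_CLA_CLA",
                                    "k_AP_lipid"),
                         c(p$KD_CC, p$KD_AC, p$dG_coop, p$dG_strain, p$h,
                           p$rho_AP, p$k_AP_CLA, p$k_CLA_CLA,
                           p$k_AP_lipid)), collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(traj$frames), con, row.names = FALSE)
  invisible(path)
}

#' Read trajectory frames written by [write_trajectory_csv()]
#' @param path CSV file.
#' @return A list: `frames` tibble, `meta` (header key-values).
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- sub("^# ", "", lines[hdr])
  frames <- utils::read.csv(text = lines[-hdr])
  list(frames = as_tibble(frames), meta = meta)
}

#' Serialize a molecule template to JSON
#' @param tpl A `molecule_template`. @param path Output file (NULL returns
#'   the JSON string).
#' @return The path or JSON string.
#' @export
write_template_json <- function(tpl, path = NULL) {
  obj <- list(name = tpl$name,
              interfaces = as.data.frame(tpl$interfaces),
              D_trans_um2s = tpl$D_trans, D_rot_rad2us = tpl$D_rot,
              com_exclusion_nm = tpl$com_exclusion_nm,
              pucker_deg = tpl$pucker)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a molecule template from JSON
#' @param path JSON file (or literal JSON string).
#' @return A `molecule_template`.
#' @export
read_template_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new_molecule_template(obj$name, as_tibble(obj$interfaces),
                        obj$D_trans_um2s, obj$D_rot_rad2us,
                        com_exclusion_nm = obj$com_exclusion_nm,
                        pucker = obj$pucker_deg)
}

#' Write a complex (or final simulation state) as XYZ
#'
#' One pseudo-atom per interface site plus one per molecule COM. Element
#' labels encode the site class.
#'
#' @param cx An `rd_complex`. @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cx, path) {
  sp <- site_positions(cx)
  com <- com_positions(cx)
  n <- nrow(sp) + nrow(com)
  lines <- c(as.character(n), "rigid-assembly snapshot (nm)")
  el <- c(cla_leg = "C", cla_ap = "N", ap_cla = "O", ap_lip = "P",
          A = "A", B = "B")
  lines <- c(lines,
             sprintf("%s %.4f %.4f %.4f", el[sp$class], sp$x, sp$y, sp$z),
             sprintf("X %.4f %.4f %.4f", com[, 1], com[, 2], com[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a complex as a minimal PDB
#' @param cx An `rd_complex`. @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(cx, path) {
  sp <- site_positions(cx)
  com <- com_positions(cx)
  rec <- character(0)
  i <- 0
  emit <- function(name, resn, resi, x, y, z) {
    i <<- i + 1
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, substr(name, 1, 4), substr(resn, 1, 3), resi, x, y, z)
  }
  for (r in seq_len(nrow(sp))) {
    rec <- c(rec, emit(sp$name[r], toupper(substr(sp$class[r], 1, 3)),
                       sp$mol[r], sp$x[r], sp$y[r], sp$z[r]))
  }
  for (r in seq_len(nrow(com))) {
    rec <- c(rec, emit("COM", "COM", r, com[r, 1], com[r, 2], com[r, 3]))
  }
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Write a triangle mesh as OFF
#' @param mesh A `tri_mesh`. @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  lines <- c("OFF", paste(nrow(v), nrow(f), 0),
             sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a scenario configuration as JSON
#' @param scenario A `scenario_config`. @param path Output file (NULL
#'   returns the string).
#' @return The path or JSON string.
#' @export
write_scenario_json <- function(scenario, path = NULL) {
  obj <- unclass(scenario)
  obj$params <- unclass(obj$params)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a scenario configuration from JSON
#' @param path JSON file or string.
#' @return A `scenario_config`.
#' @export
read_scenario_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  pr <- obj$params
  obj$params <- do.call(model_params,
    pr[intersect(names(pr), names(formals(model_params)))])
  structure(obj, class = "scenario_config")
}
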
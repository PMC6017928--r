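# Independent SASA oracle: biotite's Shrake-Rupley implementation, called
# through the system python with the same per-atom radii, probe and point
# count. Returns the total SASA in A^2, or NA if python/biotite is not
# usable on this machine.
biotite_sasa <- function(pdb_path, radii, probe = 1.4, n_points = 960) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NA_real_)
  script <- tempfile(fileext = ".py")
  radii_txt <- paste(sprintf("%.6f", radii), collapse = ",")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "import biotite.structure.io.pdb as pdbio",
    "import biotite.structure as struc",
    sprintf("f = pdbio.PDBFile.read(r'%s')", pdb_path),
    "arr = pdbio.get_structure(f, model=1)",
    sprintf("radii = np.array([%s])", radii_txt),
    sprintf("a = struc.sasa(arr, probe_radius=%f, point_number=%d, vdw_radii=radii)",
            probe, n_points),
    "print(float(np.nansum(a)))"
  ), script)
  out <- tryCatch(
    system2(py, script, stdout = TRUE, stderr = TRUE),
    error = function(e) NULL, warning = function(w) NULL
  )
  val <- suppressWarnings(as.numeric(out[length(out)]))
  if (length(val) != 1 || !is.finite(val)) return(NA_real_)
  val
}
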
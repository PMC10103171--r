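# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit so generators behave as pure functions of (spec, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hdx <- function(kind, fmt, ...) {
  stop(structure(
    class = c(paste0("hdx_", kind, "_error"), "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA1TO3 <- structure(names(AA3TO1), names = unname(AA3TO1))

# Boltzmann constant times Avogadro's number, kJ/(mol K)
KB_KJ_MOL_K <- 0.008314462618

# Full-precision numeric formatting so CSV round trips are bit exact.
format_full <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}
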
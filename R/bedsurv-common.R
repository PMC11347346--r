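# Shared constants and small utilities used across modules.

cohort_sites <- c("Esophagus", "Hypopharynx", "Larynx", "Lip_Oral_Cavity",
                  "Nasal_Cavity", "Oropharynx")

cohort_covariates <- c("Age", "Sex", "Smoking_PY", "Stage_numeric",
                       "HPV_Positive", "HPV_Unknown", "Chemo", "RT_year")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
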
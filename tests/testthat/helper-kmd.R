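# Shared fixtures, built in code at test time.

alcohol_params <- function() mm_params(175, 11.8)

# noiseless worked-example curve across its elimination phase
noiseless_example <- function(n = 49) {
  p <- alcohol_params()
  c0 <- conc_at_fraction(0.95, p$km)
  generate_tk_dataset(p, c0, seq(0, elimination_span(p, c0), length.out = n))
}

# short-but-adequate MCMC settings for unit tests (acceptance tests use the
# package defaults)
quick_fit <- function(data, ...) {
  fit_mm_bayes(data, chains = 2, warmup = 600, draws = 800, ...)
}

cli_script <- function() {
  path <- system.file("cli", "kmd_tool.R", package = "kmdregion")
  stopifnot(nzchar(path))
  path
}

run_cli <- function(args, dir = ".") {
  withr::with_dir(dir, {
    out <- suppressWarnings(system2("Rscript", c(cli_script(), args),
                                    stdout = TRUE, stderr = TRUE))
    list(status = attr(out, "status") %||% 0L, output = paste(out, collapse = "\n"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
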
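.method_registry <- new.env(parent = emptyenv())

#' Register a batch-correction method
#'
#' Methods follow a uniform contract: a function
#' `f(table, batch_key, seed, ...)` returning a [profile_table] (optionally
#' carrying `attr(, "output_space") = "embedding"`). Registered methods are
#' invocable by name from [run_benchmark()], so external tools (scVI, DESC,
#' Seurat, Scanorama, fastMNN wrappers, ...) can be plugged in and scored
#' through the same pipeline.
#'
#' @param name Unused method name.
#' @param fn Correction function obeying the contract.
#' @param output_space `"feature"` or `"embedding"`.
#' @param overwrite Allow replacing an existing registration.
#' @return `name`, invisibly.
#' @export
register_method <- function(name, fn, output_space = c("feature", "embedding"),
                            overwrite = FALSE) {
  output_space <- match.arg(output_space)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.function(fn)) stop("fn must be a function")
  if (!overwrite && name %in% ls(.method_registry)) {
    stop("method '", name, "' is already registered")
  }
  assign(name, list(fn = fn, output_space = output_space),
         envir = .method_registry)
  invisible(name)
}

#' @rdname register_method
#' @export
list_methods <- function() sort(ls(.method_registry))

#' @rdname register_method
#' @export
get_method <- function(name) {
  if (!name %in% ls(.method_registry)) {
    stop("unknown correction method: '", name, "' (registered: ",
         paste(list_methods(), collapse = ", "), ")")
  }
  get(name, envir = .method_registry)
}

register_builtin_methods <- function() {
  register_method("baseline", function(table, batch_key, seed = 1, ...) {
    baseline_identity(table, batch_key)
  }, "feature", overwrite = TRUE)
  register_method("sphering", function(table, batch_key, seed = 1,
                                       lambda = 1, ...) {
    sphering_correct(table, batch_key, lambda = lambda)
  }, "feature", overwrite = TRUE)
  register_method("combat", function(table, batch_key, seed = 1, ...) {
    combat_correct(table, batch_key)
  }, "feature", overwrite = TRUE)
  register_method("mnn", function(table, batch_key, seed = 1, k = 20, ...) {
    mnn_correct(table, batch_key, k = k)
  }, "feature", overwrite = TRUE)
  register_method("harmony", function(table, batch_key, seed = 1, ...) {
    harmony_lite(table, batch_key, seed = seed, ...)
  }, "embedding", overwrite = TRUE)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_methods()
}
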
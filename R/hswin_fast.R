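# Glue between the R model handle and the single-precision compute core.
# The core runs the identical computation graph in float32; the double
# precision R path (hswin_forward / hswin_backward) is the reference
# implementation and the two are cross-checked in the test suite.

# plan in the flat form the C++ core consumes (cached per shape)
cplan_for <- function(model, dims, B) {
  key <- paste("c", paste(dims, collapse = "x"), B, sep = "_")
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  plan <- get_plan(model, dims)
  cfg <- model$cfg
  stages <- lapply(plan$stages, function(sp) {
    list(N = as.integer(sp$N), ws = as.integer(sp$ws),
         nwin = as.integer(sp$nwin), can_shift = isTRUE(sp$can_shift),
         perm0 = as.integer(sp$perm0),
         perm_s = if (isTRUE(sp$can_shift)) as.integer(sp$perm_s) else integer(0),
         mask = if (isTRUE(sp$can_shift)) sp$mask else numeric(0),
         relidx = as.integer(sp$relidx))
  })
  cp <- list(dims = as.integer(dims), nvox = as.integer(plan$nvox),
             B = as.integer(B), n_classes = cfg$num_classes,
             depths = cfg$depths, sdims = cfg$stage_dims, heads = cfg$heads,
             hidden = as.integer(round(cfg$stage_dims * cfg$mlp_ratio)),
             hybrid = cfg$hybrid, n_dil = length(cfg$dilation_rates),
             conv_channels = cfg$conv_channels,
             fused_channels = cfg$fused_channels,
             embed_idx = plan$embed_idx,
             merge_idx = plan$merge_idx,
             stages = stages,
             conv = if (cfg$hybrid) lapply(plan$conv, function(c_)
               list(idx = c_$idx, pd = as.integer(c_$padded_dims),
                    dil = as.integer(c_$dilation))) else list())
  model$cache[[key]] <- cp
  cp
}

# forward-only fast pass: returns logits ((B*nvox) x classes)
fast_forward <- function(model, xs) {
  cp <- cplan_for(model, dim(xs[[1]]), length(xs))
  hswin_pass_cpp(model$params, cp, xs, integer(0), FALSE)$logits
}

# fused forward+backward+loss; y is the 0/1 label vector (B*nvox)
fast_step <- function(model, xs, y) {
  cp <- cplan_for(model, dim(xs[[1]]), length(xs))
  res <- hswin_pass_cpp(model$params, cp, xs, as.integer(y), TRUE)
  g <- res$grads
  for (nm in names(g))
    if (is.null(dim(model$params[[nm]]))) g[[nm]] <- as.numeric(g[[nm]])
  res$grads <- g
  res
}
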
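# small seascape configurations used across test files
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(width = 20000, height = 15000, cell_size = 1000,
         n_grab = 120, n_video = 50),
    list(...))
  do.call(seascape_config, args)
}
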
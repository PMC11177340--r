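// Pin BLAS to a single thread: the engine issues many small GEMMs where
// OpenBLAS thread synchronisation costs more than the arithmetic.
#include <Rcpp.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif

// [[Rcpp::export]]
bool blas_single_thread() {
#ifndef _WIN32
  typedef void (*setter)(int);
  setter f = (setter) dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f == NULL) f = (setter) dlsym(RTLD_DEFAULT, "goto_set_num_threads");
  if (f != NULL) { f(1); return true; }
#endif
  return false;
}
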
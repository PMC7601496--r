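// Direct access to the core's noise generator, for statistical tests and
// for documenting the stream-splitting contract.

#include <Rcpp.h>
#include "rng.h"

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_rng_normals(double seed, double stream, int n) {
    ffsrng::Rng rng(static_cast<std::uint64_t>(seed),
                    static_cast<std::uint64_t>(stream));
    NumericVector out(n);
    for (int i = 0; i < n; i++) out[i] = rng.normal();
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_rng_uniforms(double seed, double stream, int n) {
    ffsrng::Rng rng(static_cast<std::uint64_t>(seed),
                    static_cast<std::uint64_t>(stream));
    NumericVector out(n);
    for (int i = 0; i < n; i++) out[i] = rng.unif();
    return out;
}
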
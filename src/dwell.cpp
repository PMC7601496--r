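// 1D quartic double-well particle, V(x) = h (x^2 - 1)^2, integrated with the
// same Langevin scheme as the chain core.  Order parameter is -x so that
// "forward" progress (A -> B) decreases the order parameter, matching the
// contact-number convention of the desorption problem.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include "rng.h"

using namespace Rcpp;

static const double KB = 0.0083144626; // kJ/mol/K

// [[Rcpp::export]]
List cpp_dw_run(double x0, double v0, double h, double mass, double temp,
                double dt, double tdamp, double seed, double stream,
                double max_steps, double op_lo, double op_hi,
                int record_stride) {
    ffsrng::Rng rng(static_cast<std::uint64_t>(seed),
                    static_cast<std::uint64_t>(stream));
    const double gam = mass / tdamp;
    const double nstd = std::sqrt(2.0 * mass * KB * temp / (tdamp * dt));
    const double hh = 0.5 * dt / mass;
    const bool use_lo = !ISNAN(op_lo), use_hi = !ISNAN(op_hi);
    const std::int64_t nmax = static_cast<std::int64_t>(max_steps);

    double x = x0, v = v0;
    auto fcons = [&](double xx) { return -4.0 * h * xx * (xx * xx - 1.0); };
    double ft = fcons(x) - gam * v + nstd * rng.normal();
    double op = -x, opmin = op;
    std::string why = "maxsteps";
    std::int64_t step = 0;
    std::vector<double> rec;
    const bool rec_on = record_stride > 0;
    if (rec_on) { rec.push_back(0.0); rec.push_back(op); }

    bool done = (use_lo && op < op_lo) || (use_hi && op >= op_hi);
    if (done) why = (use_lo && op < op_lo) ? "lo" : "hi";
    while (!done && step < nmax) {
        v += hh * ft;
        x += dt * v;
        ft = fcons(x) - gam * v + nstd * rng.normal();
        v += hh * ft;
        step++;
        op = -x;
        if (op < opmin) opmin = op;
        if (rec_on && step % record_stride == 0) {
            rec.push_back(dt * step);
            rec.push_back(op);
        }
        if (use_lo && op < op_lo) { why = "lo"; break; }
        if (use_hi && op >= op_hi) { why = "hi"; break; }
        if (step % 8388608 == 0) Rcpp::checkUserInterrupt();
    }

    List out = List::create(_["x"] = x, _["v"] = v, _["steps"] = (double)step,
                            _["time"] = dt * step, _["stop"] = why,
                            _["op"] = op, _["min_op"] = opmin);
    if (rec_on) {
        int nrow = rec.size() / 2;
        NumericMatrix rm(nrow, 2);
        for (int r = 0; r < nrow; r++) {
            rm(r, 0) = rec[2 * r];
            rm(r, 1) = rec[2 * r + 1];
        }
        colnames(rm) = CharacterVector::create("time", "C");
        out["record"] = rm;
    }
    return out;
}

// [[Rcpp::export]]
List cpp_dw_crossings(double x0, double v0, double h, double mass, double temp,
                      double dt, double tdamp, double seed, double stream,
                      double n_steps, double lamA, double lam0, double lamB,
                      int max_snapshots) {
    ffsrng::Rng rng(static_cast<std::uint64_t>(seed),
                    static_cast<std::uint64_t>(stream));
    const double gam = mass / tdamp;
    const double nstd = std::sqrt(2.0 * mass * KB * temp / (tdamp * dt));
    const double hh = 0.5 * dt / mass;
    double x = x0, v = v0;
    auto fcons = [&](double xx) { return -4.0 * h * xx * (xx * xx - 1.0); };
    double ft = fcons(x) - gam * v + nstd * rng.normal();
    double op = -x;

    bool armed = op < lamA;
    int mode = op < lamB ? 1 : 0;
    std::int64_t elig = 0;
    std::vector<double> times, sx, sv;
    const std::int64_t nmax = static_cast<std::int64_t>(n_steps);

    for (std::int64_t step = 1; step <= nmax; step++) {
        v += hh * ft;
        x += dt * v;
        ft = fcons(x) - gam * v + nstd * rng.normal();
        v += hh * ft;
        double opprev = op;
        op = -x;
        if (mode == 0) {
            elig++;
            if (op < lamB) {
                mode = 1;
                armed = false;
            } else {
                if (!armed && opprev >= lamA && op < lamA) armed = true;
                if (armed && op < lam0) {
                    times.push_back(dt * step);
                    if ((int)sx.size() < max_snapshots) {
                        sx.push_back(x);
                        sv.push_back(v);
                    }
                    armed = false;
                }
            }
        } else if (mode == 1) {
            if (op >= lamB) mode = 2;
        } else {
            if (op < lamB) mode = 1;
            else if (op >= lamA) { mode = 0; armed = false; }
        }
        if (step % 8388608 == 0) Rcpp::checkUserInterrupt();
    }

    return List::create(_["n_crossings"] = (double)times.size(),
                        _["times"] = times, _["snap_x"] = sx,
                        _["snap_v"] = sv,
                        _["eligible_time"] = dt * (double)elig,
                        _["total_time"] = dt * (double)nmax,
                        _["final_op"] = op);
}
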
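// Langevin dynamics core for a single coarse-grained bead-spring chain near
// an attractive flat wall (Steele 10-4-3), plus a 1D double-well particle
// used to validate the rare-event machinery.
//
// Units: kJ/mol (energy), nm (length), ps (time), g/mol (mass), K.
// In this system a = F/m comes out directly in nm/ps^2 and
// (1/2) m v^2 in kJ/mol, so no conversion constants appear.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include "rng.h"

using namespace Rcpp;

static const double KB = 0.0083144626; // kJ/mol/K

// ---------------------------------------------------------------------------
// model parameters
// ---------------------------------------------------------------------------

struct Model {
    int N;
    double m, lb, kb, kA, thetaA, kD, rD, sPP, ePP, sPW, ePW;
    bool use_ev, use_angle, use_tors, wall_on;
    double lj_cut2, lj_shift;
    // switching function (contact number)
    double d0, r0;
    int sn, sm;
};

static Model parse_model(const List &ml, bool wall_on) {
    Model M;
    M.N = as<int>(ml["N"]);
    M.m = as<double>(ml["m"]);
    M.lb = as<double>(ml["lb"]);
    M.kb = as<double>(ml["kb"]);
    M.kA = as<double>(ml["kA"]);
    M.thetaA = as<double>(ml["thetaA_rad"]);
    M.kD = as<double>(ml["kD"]);
    M.rD = as<double>(ml["rD"]);
    M.sPP = as<double>(ml["sPP"]);
    M.ePP = as<double>(ml["ePP"]);
    M.sPW = as<double>(ml["sPW"]);
    M.ePW = as<double>(ml["ePW"]);
    M.use_ev = as<bool>(ml["use_ev"]);
    M.use_angle = as<bool>(ml["use_angle"]);
    M.use_tors = as<bool>(ml["use_torsionlike"]);
    M.wall_on = wall_on && M.ePW != 0.0;
    double rc = 2.5 * M.sPP;
    M.lj_cut2 = rc * rc;
    double ir6 = std::pow(1.0 / 2.5, 6);
    M.lj_shift = 4.0 * M.ePP * (ir6 * ir6 - ir6);
    List sw = ml["switching"];
    M.d0 = as<double>(sw["d0"]);
    M.r0 = as<double>(sw["r0"]);
    M.sn = as<int>(sw["n"]);
    M.sm = as<int>(sw["m_exp"]);
    return M;
}

// ---------------------------------------------------------------------------
// switching function / contact number
// ---------------------------------------------------------------------------

static inline double ipow(double x, int n) {
    double r = 1.0;
    while (n > 0) {
        if (n & 1) r *= x;
        x *= x;
        n >>= 1;
    }
    return r;
}

// rational switch s(z) = (1 - x^n)/(1 - x^m), x = (z - d0)/r0, clamped to 1
// below the onset distance d0; the removable singularity at x = 1 is n/m.
// The default exponents (6, 14) take a fast multiplication-only path.
static inline double switch_s(double z, const Model &M) {
    if (z <= M.d0) return 1.0;
    double x = (z - M.d0) / M.r0;
    if (std::fabs(x - 1.0) < 1e-8)
        return static_cast<double>(M.sn) / static_cast<double>(M.sm);
    if (M.sn == 6 && M.sm == 14) {
        double x2 = x * x, x6 = x2 * x2 * x2;
        return (1.0 - x6) / (1.0 - x6 * x6 * x2);
    }
    return (1.0 - ipow(x, M.sn)) / (1.0 - ipow(x, M.sm));
}

static inline double contact_C(const std::vector<double> &x, const Model &M) {
    double C = 0.0;
    for (int i = 0; i < M.N; i++) C += switch_s(x[3 * i + 2], M);
    return C;
}

// ---------------------------------------------------------------------------
// Steele 10-4-3 wall
// ---------------------------------------------------------------------------

static inline double wall_V(double z, double s, double e) {
    double u = s / z;
    double u2 = u * u, u4 = u2 * u2, u10 = u4 * u4 * u2;
    double c = 0.61 * s / M_SQRT2;
    double zc = z + c;
    return 2.0 * M_PI * e *
           (0.4 * u10 - u4 - M_SQRT2 * s * s * s / (3.0 * zc * zc * zc));
}

// dV/dz (force on the bead is -dV/dz)
static inline double wall_dV(double z, double s, double e) {
    double s4 = s * s * s * s;
    double s10 = s4 * s4 * s * s;
    double z5 = z * z * z * z * z;
    double z11 = z5 * z5 * z;
    double c = 0.61 * s / M_SQRT2;
    double zc = z + c;
    double zc4 = zc * zc * zc * zc;
    return 2.0 * M_PI * e *
           (-4.0 * s10 / z11 + 4.0 * s4 / z5 + M_SQRT2 * s * s * s / zc4);
}

// ---------------------------------------------------------------------------
// neighbour list (Verlet list with skin, O(N^2) rebuild)
// ---------------------------------------------------------------------------

struct NeighList {
    double skin = 0.3;       // nm
    double rlist2 = 0.0;
    std::vector<int> pairs;  // flat (i, j)
    std::vector<double> xref;
    bool valid = false;

    void build(const std::vector<double> &x, const Model &M) {
        double rl = std::sqrt(M.lj_cut2) + skin;
        rlist2 = rl * rl;
        pairs.clear();
        for (int i = 0; i < M.N - 2; i++) {
            for (int j = i + 2; j < M.N; j++) {
                double dx = x[3 * i] - x[3 * j];
                double dy = x[3 * i + 1] - x[3 * j + 1];
                double dz = x[3 * i + 2] - x[3 * j + 2];
                if (dx * dx + dy * dy + dz * dz < rlist2) {
                    pairs.push_back(i);
                    pairs.push_back(j);
                }
            }
        }
        xref = x;
        valid = true;
    }

    bool stale(const std::vector<double> &x, int N) const {
        if (!valid) return true;
        double lim = 0.25 * skin * skin; // (skin/2)^2
        for (int i = 0; i < 3 * N; i++) {
            double d = x[i] - xref[i];
            if (d * d > lim) return true; // per-component bound is conservative
        }
        return false;
    }
};

// ---------------------------------------------------------------------------
// potential energy and forces (exact negative gradient)
// ---------------------------------------------------------------------------

static double forces(const std::vector<double> &x, std::vector<double> &f,
                     const Model &M, NeighList &nl) {
    const int N = M.N;
    double E = 0.0;
    std::fill(f.begin(), f.end(), 0.0);

    // harmonic bonds: kb (r - lb)^2
    for (int i = 0; i < N - 1; i++) {
        double dx = x[3 * i] - x[3 * (i + 1)];
        double dy = x[3 * i + 1] - x[3 * (i + 1) + 1];
        double dz = x[3 * i + 2] - x[3 * (i + 1) + 2];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double dr = r - M.lb;
        E += M.kb * dr * dr;
        double fac = -2.0 * M.kb * dr / r;
        f[3 * i] += fac * dx;
        f[3 * i + 1] += fac * dy;
        f[3 * i + 2] += fac * dz;
        f[3 * (i + 1)] -= fac * dx;
        f[3 * (i + 1) + 1] -= fac * dy;
        f[3 * (i + 1) + 2] -= fac * dz;
    }

    // harmonic bending: kA (theta - thetaA)^2
    if (M.use_angle && M.kA > 0.0) {
        for (int j = 1; j < N - 1; j++) {
            int i1 = j - 1, i2 = j, i3 = j + 1;
            double d1x = x[3 * i1] - x[3 * i2];
            double d1y = x[3 * i1 + 1] - x[3 * i2 + 1];
            double d1z = x[3 * i1 + 2] - x[3 * i2 + 2];
            double d2x = x[3 * i3] - x[3 * i2];
            double d2y = x[3 * i3 + 1] - x[3 * i2 + 1];
            double d2z = x[3 * i3 + 2] - x[3 * i2 + 2];
            double rsq1 = d1x * d1x + d1y * d1y + d1z * d1z;
            double rsq2 = d2x * d2x + d2y * d2y + d2z * d2z;
            double r1 = std::sqrt(rsq1), r2 = std::sqrt(rsq2);
            double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
            if (c > 1.0) c = 1.0;
            if (c < -1.0) c = -1.0;
            double s = std::sqrt(1.0 - c * c);
            if (s < 1e-8) s = 1e-8;
            double dtheta = std::acos(c) - M.thetaA;
            E += M.kA * dtheta * dtheta;
            double a = -2.0 * M.kA * dtheta / s;
            double a11 = a * c / rsq1;
            double a12 = -a / (r1 * r2);
            double a22 = a * c / rsq2;
            double f1x = a11 * d1x + a12 * d2x;
            double f1y = a11 * d1y + a12 * d2y;
            double f1z = a11 * d1z + a12 * d2z;
            double f3x = a22 * d2x + a12 * d1x;
            double f3y = a22 * d2y + a12 * d1y;
            double f3z = a22 * d2z + a12 * d1z;
            f[3 * i1] += f1x;
            f[3 * i1 + 1] += f1y;
            f[3 * i1 + 2] += f1z;
            f[3 * i3] += f3x;
            f[3 * i3 + 1] += f3y;
            f[3 * i3 + 2] += f3z;
            f[3 * i2] -= f1x + f3x;
            f[3 * i2 + 1] -= f1y + f3y;
            f[3 * i2 + 2] -= f1z + f3z;
        }
    }

    // torsion-like 1-4 distance springs: kD (r_{i,i+3} - rD)^2
    if (M.use_tors && M.kD > 0.0) {
        for (int i = 0; i < N - 3; i++) {
            int j = i + 3;
            double dx = x[3 * i] - x[3 * j];
            double dy = x[3 * i + 1] - x[3 * j + 1];
            double dz = x[3 * i + 2] - x[3 * j + 2];
            double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            double dr = r - M.rD;
            E += M.kD * dr * dr;
            double fac = -2.0 * M.kD * dr / r;
            f[3 * i] += fac * dx;
            f[3 * i + 1] += fac * dy;
            f[3 * i + 2] += fac * dz;
            f[3 * j] -= fac * dx;
            f[3 * j + 1] -= fac * dy;
            f[3 * j + 2] -= fac * dz;
        }
    }

    // excluded volume: 12-6 LJ for |i-j| >= 2, cut at 2.5 sigma, shifted
    if (M.use_ev && M.ePP > 0.0) {
        if (nl.stale(x, N)) nl.build(x, M);
        double s2 = M.sPP * M.sPP;
        for (size_t k = 0; k < nl.pairs.size(); k += 2) {
            int i = nl.pairs[k], j = nl.pairs[k + 1];
            double dx = x[3 * i] - x[3 * j];
            double dy = x[3 * i + 1] - x[3 * j + 1];
            double dz = x[3 * i + 2] - x[3 * j + 2];
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 >= M.lj_cut2) continue;
            if (r2 < 1e-12) stop("overlapping beads (r = 0) in LJ interaction");
            double ir2 = s2 / r2;
            double ir6 = ir2 * ir2 * ir2;
            double ir12 = ir6 * ir6;
            E += 4.0 * M.ePP * (ir12 - ir6) - M.lj_shift;
            double fac = 24.0 * M.ePP * (2.0 * ir12 - ir6) / r2;
            f[3 * i] += fac * dx;
            f[3 * i + 1] += fac * dy;
            f[3 * i + 2] += fac * dz;
            f[3 * j] -= fac * dx;
            f[3 * j + 1] -= fac * dy;
            f[3 * j + 2] -= fac * dz;
        }
    }

    // wall (energy and -dV/dz with two divisions per bead)
    if (M.wall_on) {
        const double s = M.sPW, e2pi = 2.0 * M_PI * M.ePW;
        const double inv_s = 1.0 / s, s3 = s * s * s;
        const double c = 0.61 * s / M_SQRT2;
        for (int i = 0; i < N; i++) {
            double z = x[3 * i + 2];
            double u = s / z;
            double u2 = u * u, u4 = u2 * u2, u5 = u4 * u, u10 = u5 * u5;
            double w = 1.0 / (z + c), w3 = w * w * w;
            E += e2pi * (0.4 * u10 - u4 - M_SQRT2 * s3 * w3 / 3.0);
            f[3 * i + 2] -= e2pi * ((4.0 * u4 * u - 4.0 * u10 * u) * inv_s +
                                    M_SQRT2 * s3 * w3 * w);
        }
    }

    return E;
}

// ---------------------------------------------------------------------------
// integrator: velocity Verlet with impulsive Langevin friction + noise
// (LAMMPS "fix langevin" style; friction uses the half-step velocity)
// ---------------------------------------------------------------------------

struct Lang {
    double temp, dt, tdamp, nstd, gam;
    Lang(double T, double dt_, double td, double mass)
        : temp(T), dt(dt_), tdamp(td) {
        nstd = std::sqrt(2.0 * mass * KB * T / (td * dt_));
        gam = mass / td;
    }
};

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, List model, bool wall_on) {
    Model M = parse_model(model, wall_on);
    if (pos.nrow() != M.N || pos.ncol() != 3)
        stop("positions must be an N x 3 matrix matching the model");
    std::vector<double> x(3 * M.N), f(3 * M.N);
    for (int i = 0; i < M.N; i++)
        for (int d = 0; d < 3; d++) x[3 * i + d] = pos(i, d);
    NeighList nl;
    double E = forces(x, f, M, nl);
    NumericMatrix fo(M.N, 3);
    for (int i = 0; i < M.N; i++)
        for (int d = 0; d < 3; d++) fo(i, d) = f[3 * i + d];
    return List::create(_["energy"] = E, _["forces"] = fo,
                        _["contact"] = contact_C(x, M));
}

// [[Rcpp::export]]
NumericVector cpp_switching(NumericVector z, double d0, double r0, int n,
                            int m_exp) {
    Model M;
    M.d0 = d0;
    M.r0 = r0;
    M.sn = n;
    M.sm = m_exp;
    NumericVector out(z.size());
    for (R_xlen_t i = 0; i < z.size(); i++) out[i] = switch_s(z[i], M);
    return out;
}

// Shared driver.  Stop conditions (any may be NA = disabled):
//   c_lo:    stop when contact number C <  c_lo   ("lo")
//   c_hi:    stop when C >= c_hi                  ("hi")
//   z_far:   stop when the chain COM z >= z_far   ("far")
// Always stops at max_steps ("maxsteps").  State is returned at the first
// step satisfying a condition (first-touch convention).
// record_mode: 0 none, 1 contact trace, 2 full thermo trace
// [[Rcpp::export]]
List cpp_chain_run(NumericMatrix pos, NumericMatrix vel, List model,
                   bool wall_on, double temp, double dt, double tdamp,
                   double seed, double stream, double max_steps, double c_lo,
                   double c_hi, double z_far, int record_mode,
                   int record_stride) {
    Model M = parse_model(model, wall_on);
    const int N = M.N;
    if (pos.nrow() != N || vel.nrow() != N)
        stop("positions/velocities must be N x 3 matrices matching the model");
    Lang L(temp, dt, tdamp, M.m);
    ffsrng::Rng rng(static_cast<std::uint64_t>(seed),
                    static_cast<std::uint64_t>(stream));

    std::vector<double> x(3 * N), v(3 * N), fc(3 * N), ft(3 * N);
    for (int i = 0; i < N; i++)
        for (int d = 0; d < 3; d++) {
            x[3 * i + d] = pos(i, d);
            v[3 * i + d] = vel(i, d);
        }

    NeighList nl;
    const bool use_lo = !ISNAN(c_lo), use_hi = !ISNAN(c_hi),
               use_far = !ISNAN(z_far);
    const std::int64_t nmax = static_cast<std::int64_t>(max_steps);

    std::vector<double> rec;
    const bool rec_on = record_mode > 0 && record_stride > 0;
    const int rec_cols = record_mode == 2 ? 10 : 2;

    double E = forces(x, fc, M, nl);
    double C = contact_C(x, M);
    double cmin = C, csum = C;

    auto com = [&](int d) {
        double s = 0.0;
        for (int i = 0; i < N; i++) s += x[3 * i + d];
        return s / N;
    };
    auto ekin = [&]() {
        double s = 0.0;
        for (int i = 0; i < 3 * N; i++) s += v[i] * v[i];
        return 0.5 * M.m * s;
    };
    auto record = [&](double t) {
        rec.push_back(t);
        rec.push_back(C);
        if (record_mode == 2) {
            rec.push_back(E);
            rec.push_back(ekin());
            rec.push_back(com(0));
            rec.push_back(com(1));
            rec.push_back(com(2));
            rec.push_back(x[3 * (N - 1)] - x[0]);
            rec.push_back(x[3 * (N - 1) + 1] - x[1]);
            rec.push_back(x[3 * (N - 1) + 2] - x[2]);
        }
    };

    std::string why = "maxsteps";
    std::int64_t step = 0;
    if (rec_on) record(0.0);

    auto stopped = [&]() -> bool {
        if (use_lo && C < c_lo) { why = "lo"; return true; }
        if (use_hi && C >= c_hi) { why = "hi"; return true; }
        if (use_far && com(2) >= z_far) { why = "far"; return true; }
        return false;
    };

    bool done = stopped(); // the initial state may already satisfy a condition
    if (!done) {
        // total force at t=0 (fresh noise, friction on current velocity)
        for (int i = 0; i < 3 * N; i++)
            ft[i] = fc[i] - L.gam * v[i] + L.nstd * rng.normal();
        const double h = 0.5 * dt / M.m;
        while (step < nmax) {
            for (int i = 0; i < 3 * N; i++) {
                v[i] += h * ft[i];
                x[i] += dt * v[i];
            }
            E = forces(x, fc, M, nl);
            for (int i = 0; i < 3 * N; i++)
                ft[i] = fc[i] - L.gam * v[i] + L.nstd * rng.normal();
            for (int i = 0; i < 3 * N; i++) v[i] += h * ft[i];
            step++;
            C = contact_C(x, M);
            if (C < cmin) cmin = C;
            csum += C;
            if (!std::isfinite(C) || !std::isfinite(x[2]))
                stop("integration failure: non-finite coordinates at step %ld",
                     (long)step);
            if (M.wall_on) {
                for (int i = 0; i < N; i++)
                    if (x[3 * i + 2] <= 0.0)
                        stop("integration failure: bead penetrated the wall");
            }
            if (rec_on && (step % record_stride == 0)) record(dt * step);
            if (stopped()) break;
            if (step % 1048576 == 0) Rcpp::checkUserInterrupt();
        }
    }

    NumericMatrix po(N, 3), vo(N, 3);
    for (int i = 0; i < N; i++)
        for (int d = 0; d < 3; d++) {
            po(i, d) = x[3 * i + d];
            vo(i, d) = v[3 * i + d];
        }
    List out = List::create(
        _["positions"] = po, _["velocities"] = vo, _["steps"] = (double)step,
        _["time"] = dt * step, _["stop"] = why, _["contact"] = C,
        _["min_contact"] = cmin, _["mean_contact"] = csum / (step + 1.0),
        _["energy"] = E);
    if (rec_on) {
        int nrow = rec.size() / rec_cols;
        NumericMatrix rm(nrow, rec_cols);
        for (int r = 0; r < nrow; r++)
            for (int ccol = 0; ccol < rec_cols; ccol++)
                rm(r, ccol) = rec[r * rec_cols + ccol];
        colnames(rm) = record_mode == 2
            ? CharacterVector::create("time", "C", "epot", "ekin", "comx",
                                      "comy", "comz", "eex", "eey", "eez")
            : CharacterVector::create("time", "C");
        out["record"] = rm;
    }
    return out;
}

// Fixed-length run that replays a base-rate trajectory and harvests the
// armed forward crossings of lambda0 (state snapshots + times), together
// with the eligible-time bookkeeping (time in B, and in the B -> A transit,
// is excluded).
// [[Rcpp::export]]
List cpp_chain_crossings(NumericMatrix pos, NumericMatrix vel, List model,
                         double temp, double dt, double tdamp, double seed,
                         double stream, double n_steps, double lamA,
                         double lam0, double lamB, int max_snapshots) {
    Model M = parse_model(model, true);
    const int N = M.N;
    Lang L(temp, dt, tdamp, M.m);
    ffsrng::Rng rng(static_cast<std::uint64_t>(seed),
                    static_cast<std::uint64_t>(stream));

    std::vector<double> x(3 * N), v(3 * N), fc(3 * N), ft(3 * N);
    for (int i = 0; i < N; i++)
        for (int d = 0; d < 3; d++) {
            x[3 * i + d] = pos(i, d);
            v[3 * i + d] = vel(i, d);
        }

    NeighList nl;
    double E = forces(x, fc, M, nl);
    double C = contact_C(x, M);

    // crossing state machine
    bool armed = C < lamA;      // already on an excursion below the basin edge
    int mode = C < lamB ? 1 : 0; // 0 normal, 1 in B, 2 transit B -> A
    std::int64_t elig = 0;
    std::vector<double> times;
    List snaps;

    for (int i = 0; i < 3 * N; i++)
        ft[i] = fc[i] - L.gam * v[i] + L.nstd * rng.normal();
    const double h = 0.5 * dt / M.m;
    const std::int64_t nmax = static_cast<std::int64_t>(n_steps);

    for (std::int64_t step = 1; step <= nmax; step++) {
        for (int i = 0; i < 3 * N; i++) {
            v[i] += h * ft[i];
            x[i] += dt * v[i];
        }
        E = forces(x, fc, M, nl);
        for (int i = 0; i < 3 * N; i++)
            ft[i] = fc[i] - L.gam * v[i] + L.nstd * rng.normal();
        for (int i = 0; i < 3 * N; i++) v[i] += h * ft[i];
        double Cprev = C;
        C = contact_C(x, M);
        if (!std::isfinite(C))
            stop("integration failure: non-finite coordinates");

        if (mode == 0) {
            elig++;
            if (C < lamB) {
                mode = 1; // entered B; this step's time still counted above
                armed = false;
            } else {
                if (!armed && Cprev >= lamA && C < lamA) armed = true;
                if (armed && C < lam0) {
                    times.push_back(dt * step);
                    if ((int)snaps.size() < max_snapshots) {
                        NumericMatrix po(N, 3), vo(N, 3);
                        for (int i = 0; i < N; i++)
                            for (int d = 0; d < 3; d++) {
                                po(i, d) = x[3 * i + d];
                                vo(i, d) = v[3 * i + d];
                            }
                        snaps.push_back(List::create(_["positions"] = po,
                                                     _["velocities"] = vo));
                    }
                    armed = false;
                }
            }
        } else if (mode == 1) {
            if (C >= lamB) mode = 2;
        } else { // transit
            if (C < lamB) mode = 1;
            else if (C >= lamA) { mode = 0; armed = false; }
        }
        if (step % 1048576 == 0) Rcpp::checkUserInterrupt();
    }

    return List::create(_["n_crossings"] = (double)times.size(),
                        _["times"] = times, _["snapshots"] = snaps,
                        _["eligible_time"] = dt * (double)elig,
                        _["total_time"] = dt * (double)nmax,
                        _["final_contact"] = C);
}
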
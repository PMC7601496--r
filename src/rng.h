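#ifndef FFSDESORB_RNG_H
#define FFSDESORB_RNG_H

#include <cstdint>
#include <cmath>

// Counter-style reproducible RNG for the dynamics core.
// Streams are derived from a (seed, stream) pair with splitmix64 so that
// every trial / replica runs on an independent, replayable noise stream.
// Uniforms: xoshiro256++ (Blackman & Vigna). Normals: Marsaglia-Tsang
// 128-layer ziggurat with exact tail fallback.

namespace ffsrng {

inline std::uint64_t splitmix64(std::uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    std::uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

inline std::uint64_t rotl(const std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
}

struct Ziggurat {
    std::uint32_t kn[128];
    double wn[128], fn[128];
    Ziggurat() {
        const double m1 = 2147483648.0; // 2^31
        double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
        double q = vn / std::exp(-0.5 * dn * dn);
        kn[0] = static_cast<std::uint32_t>((dn / q) * m1);
        kn[1] = 0;
        wn[0] = q / m1;
        wn[127] = dn / m1;
        fn[0] = 1.0;
        fn[127] = std::exp(-0.5 * dn * dn);
        for (int i = 126; i >= 1; i--) {
            dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
            kn[i + 1] = static_cast<std::uint32_t>((dn / tn) * m1);
            tn = dn;
            fn[i] = std::exp(-0.5 * dn * dn);
            wn[i] = dn / m1;
        }
    }
};

inline const Ziggurat &zigtab() {
    static const Ziggurat z;
    return z;
}

class Rng {
  public:
    Rng(std::uint64_t seed, std::uint64_t stream) {
        // distinct (seed, stream) pairs give statistically independent states
        std::uint64_t x = seed ^ (stream * 0x9E3779B97f4A7C15ULL) ^ 0xD2B74407B1CE6E93ULL;
        for (int i = 0; i < 4; i++) s[i] = splitmix64(x);
    }

    std::uint64_t next_u64() {
        const std::uint64_t r = rotl(s[0] + s[3], 23) + s[0];
        const std::uint64_t t = s[1] << 17;
        s[2] ^= s[0];
        s[3] ^= s[1];
        s[1] ^= s[2];
        s[0] ^= s[3];
        s[2] ^= t;
        s[3] = rotl(s[3], 45);
        return r;
    }

    // uniform in (0, 1); never returns exactly 0 (safe for log())
    double unif() {
        return ((next_u64() >> 11) + 0.5) * 1.1102230246251565e-16; // * 2^-53
    }

    double normal() {
        const Ziggurat &Z = zigtab();
        for (;;) {
            const std::int32_t hz = static_cast<std::int32_t>(next_u64() >> 32);
            const std::uint32_t iz = static_cast<std::uint32_t>(hz) & 127u;
            const std::uint32_t ahz =
                hz < 0 ? static_cast<std::uint32_t>(-static_cast<std::int64_t>(hz))
                       : static_cast<std::uint32_t>(hz);
            if (ahz < Z.kn[iz]) return hz * Z.wn[iz];
            // outside the rectangle: wedge or tail
            const double r = 3.442619855899;
            double x = hz * Z.wn[iz];
            if (iz == 0) { // exact Marsaglia tail
                double y;
                do {
                    x = -std::log(unif()) / r;
                    y = -std::log(unif());
                } while (y + y < x * x);
                return hz > 0 ? r + x : -(r + x);
            }
            if (Z.fn[iz] + unif() * (Z.fn[iz - 1] - Z.fn[iz]) <
                std::exp(-0.5 * x * x))
                return x;
            // else resample
        }
    }

  private:
    std::uint64_t s[4];
};

} // namespace ffsrng

#endif
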
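// Brownian-dynamics core of the synaptic-cleft simulation.
//
// Reduced geometry: glutamate diffuses in a 20 nm extracellular slab
// (z in [0, gap]) spread over the flattened presynaptic membrane. The
// flattening maps the membrane of the axon/bouton to the (u, v) plane:
// u runs along the axon axis, v along the circumference (|v| <= pi *
// R(u), R = bouton or axon radius). The top face (z = gap) is the
// sensor-carrying membrane, discretized into one-sensor cells at the
// sensor-density pitch. The bottom face (z = 0) is the spine membrane
// (reflective) within the spine contact radius and the astrocytic
// sheath (glutamate-transporter capture with per-contact probability
// pCapture) beyond it. Axon ends (|u| > uMax) are open and absorb.
//
// All randomness comes from R's RNG so set.seed() controls runs.

#include <Rcpp.h>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Fast internal RNG (xoshiro256++), seeded from R's RNG so that
// set.seed() fully determines a run. R's norm_rand is too slow for the
// ~1e8 displacement draws of a saturation experiment.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool haveSpare = false;
  double spare = 0.0;
  double norm() {  // Marsaglia polar method, cached pair
    if (haveSpare) { haveSpare = false; return spare; }
    double x, y, s2;
    do {
      x = 2.0 * unif() - 1.0;
      y = 2.0 * unif() - 1.0;
      s2 = x * x + y * y;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = y * f;
    haveSpare = true;
    return x * f;
  }
};

}  // namespace

// [[Rcpp::export(name = ".cleftSimC")]]
List cleftSimC(int nMolecules, double gap, double uMax,
               double boutonHalfLength, double boutonRadius,
               double axonRadius, double spineRadius, double cellSize,
               double D, double dt, double pBind, double pCapture,
               double pClear, double cleftRadius, int maxSteps,
               int sampleEvery,
               IntegerVector occupancy, IntegerVector transCap,
               int nu, int nv) {
  uint64_t seed;
  {
    RNGScope scope;  // derive the stream seed from R's RNG state
    seed = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
           (uint64_t)(unif_rand() * 4294967296.0);
  }
  Xoshiro rng(seed);
  const double sdStep = std::sqrt(2.0 * D * dt);
  if (sdStep > 0.5 * gap)
    stop("dt violates the stability rule sqrt(2 D dt) <= gap/2");
  const double vGlobal = M_PI * boutonRadius;  // grid v half-extent

  std::vector<double> pu(nMolecules, 0.0), pv(nMolecules, 0.0),
      pz(nMolecules, 0.5 * gap);
  std::vector<int> alive(nMolecules), life(nMolecules);
  std::vector<char> everOut(nMolecules, 0);
  for (int i = 0; i < nMolecules; ++i) {
    alive[i] = i;
    // bulk-clearance lifetime in outside-the-cleft steps, drawn once
    // (geometric with per-step hazard pClear)
    life[i] = (pClear > 0.0)
        ? (int)std::ceil(-std::log(rng.unif()) / pClear)
        : INT_MAX;
  }
  int nActive = nMolecules, nCaptured = 0, nEscaped = 0, nBound = 0;
  int nEverOut = 0;

  std::vector<double> bindTime;
  std::vector<int> bindCell;
  std::vector<double> sampT, sampFree, sampCleft;
  std::vector<int> sampCap, sampEverOut;
  bool conserved = true;

  for (int step = 1; step <= maxSteps && nActive > 0; ++step) {
    for (int a = 0; a < nActive; ) {
      int i = alive[a];
      double u = pu[i] + sdStep * rng.norm();
      double v = pv[i] + sdStep * rng.norm();
      double z = pz[i] + sdStep * rng.norm();
      bool done = false;

      // axon ends: open boundary
      if (u > uMax || u < -uMax) {
        ++nEscaped;
        done = true;
      }

      // bulk clearance: outside the cleft the 20 nm sheath is not
      // closed -- glutamate dilutes into the surrounding tissue and is
      // taken up; modelled as a first-order loss (pre-drawn lifetime)
      if (!done && u * u + v * v >= cleftRadius * cleftRadius &&
          --life[i] <= 0) {
        ++nEscaped;
        done = true;
      }

      if (!done) {
        // membrane tube seam: reflect at the local circumference bound
        double R = (std::fabs(u) <= boutonHalfLength) ? boutonRadius
                                                      : axonRadius;
        double vMax = M_PI * R;
        if (v > vMax) v = 2.0 * vMax - v;
        else if (v < -vMax) v = -2.0 * vMax - v;
        if (v > vMax) v = vMax;          // huge step safety clamp
        else if (v < -vMax) v = -vMax;

        // bottom face: spine (reflect) or astrocyte sheath; each
        // transporter cell has finite capacity, so capture saturates
        // and glutamate spreads farther at high vesicle counts
        if (z < 0.0) {
          double r2 = u * u + v * v;
          if (r2 >= spineRadius * spineRadius) {
            int iu = (int)std::floor((u + uMax) / cellSize);
            int iv = (int)std::floor((v + vGlobal) / cellSize);
            if (iu >= 0 && iu < nu && iv >= 0 && iv < nv) {
              int id = iu + nu * iv;
              if (transCap[id] > 0 && rng.unif() < pCapture) {
                --transCap[id];
                ++nCaptured;
                done = true;
              }
            }
          }
          if (!done) z = -z;
        }
        // top face: sensor membrane
        if (!done && z > gap) {
          int iu = (int)std::floor((u + uMax) / cellSize);
          int iv = (int)std::floor((v + vGlobal) / cellSize);
          if (iu >= 0 && iu < nu && iv >= 0 && iv < nv) {
            int id = iu + nu * iv;
            if (occupancy[id] == 0 && rng.unif() < pBind) {
              occupancy[id] = 1;
              bindCell.push_back(id);
              bindTime.push_back(step * dt);
              ++nBound;
              done = true;
            }
          }
          if (!done) z = 2.0 * gap - z;
        }
        if (!done && (z < 0.0 || z > gap)) z = std::min(std::max(z, 0.0), gap);
      }

      if (!everOut[i] &&
          u * u + v * v >= cleftRadius * cleftRadius) {
        everOut[i] = 1;                  // first passage out of the cleft
        ++nEverOut;
      }
      if (done) {
        alive[a] = alive[--nActive];     // swap-remove
      } else {
        pu[i] = u; pv[i] = v; pz[i] = z;
        ++a;
      }
    }

    if (step % sampleEvery == 0 || nActive == 0) {
      int inCleft = 0;
      for (int a = 0; a < nActive; ++a) {
        int i = alive[a];
        if (pu[i] * pu[i] + pv[i] * pv[i] < cleftRadius * cleftRadius)
          ++inCleft;
      }
      sampT.push_back(step * dt);
      sampFree.push_back(nActive);
      sampCleft.push_back(inCleft);
      sampEverOut.push_back(nEverOut);
      sampCap.push_back(nCaptured + nEscaped);
      if (nActive + nBound + nCaptured + nEscaped != nMolecules)
        conserved = false;
    }
  }

  int nForced = nActive;  // survivors at maxSteps count as captured
  return List::create(
      _["bindTime"] = wrap(bindTime), _["bindCell"] = wrap(bindCell),
      _["nBound"] = nBound, _["nCaptured"] = nCaptured + nForced,
      _["nEscaped"] = nEscaped, _["nForced"] = nForced,
      _["sampleTime"] = wrap(sampT), _["freeCount"] = wrap(sampFree),
      _["cleftCount"] = wrap(sampCleft), _["removedCount"] = wrap(sampCap),
      _["everLeftCleft"] = wrap(sampEverOut), _["conserved"] = conserved);
}

// Free-space random walk helper used by the diffusion-law test:
// returns final positions of n particles after `steps` steps.
// [[Rcpp::export(name = ".freeDiffusionC")]]
NumericMatrix freeDiffusionC(int n, int steps, double D, double dt) {
  uint64_t seed;
  {
    RNGScope scope;
    seed = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
           (uint64_t)(unif_rand() * 4294967296.0);
  }
  Xoshiro rng(seed);
  const double sdStep = std::sqrt(2.0 * D * dt);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double x = 0, y = 0, z = 0;
    for (int s = 0; s < steps; ++s) {
      x += sdStep * rng.norm();
      y += sdStep * rng.norm();
      z += sdStep * rng.norm();
    }
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
  }
  return out;
}
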
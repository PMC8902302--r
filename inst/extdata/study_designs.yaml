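# Design metadata of the eight bed-rest studies the framework was developed on.
# duration_days: length of the bed-rest phase; position: 6 degree head-down
# tilt (HDT) or horizontal bed rest (HBR); scout_98: scout-view orientation
# used to locate the proximal (98%) tibia site; tibia66_detection: whether the
# 66% diaphyseal site was located manually or from a scout view;
# has_duplicate_baseline: whether two baseline pQCT scans were taken.
AGBRESA:
  year: 2019
  n_subjects: 8
  duration_days: 60
  position: HDT
  device: XCT3000
  scout_98: sagittal
  tibia66_detection: automatic
  has_duplicate_baseline: false
  muscle_sites: [MUSCLE_38, MUSCLE_66]
  bone_sites: [TIBIA_04, TIBIA_38, TIBIA_66, TIBIA_98]
BBR:
  year: 2003
  n_subjects: 10
  duration_days: 56
  position: HDT
  device: XCT2000
  scout_98: frontal
  tibia66_detection: manual
  has_duplicate_baseline: false
  muscle_sites: [MUSCLE_66]
  bone_sites: [TIBIA_04, TIBIA_38, TIBIA_66]
LTBR:
  year: 2001
  n_subjects: 9
  duration_days: 90
  position: HDT
  device: XCT2000
  scout_98: frontal
  tibia66_detection: manual
  has_duplicate_baseline: true
  muscle_sites: [MUSCLE_66]
  bone_sites: [TIBIA_04, TIBIA_66]
MEP:
  year: 2011
  n_subjects: 8
  duration_days: 21
  position: HDT
  device: XCT3000
  scout_98: frontal
  tibia66_detection: manual
  has_duplicate_baseline: false
  muscle_sites: []
  bone_sites: [TIBIA_04, TIBIA_38, TIBIA_66]
NUC:
  year: 2010
  n_subjects: 7
  duration_days: 21
  position: HDT
  device: XCT3000
  scout_98: frontal
  tibia66_detection: manual
  has_duplicate_baseline: false
  muscle_sites: []
  bone_sites: [TIBIA_04, TIBIA_38, TIBIA_66]
Planhab:
  year: 2012
  n_subjects: 13
  duration_days: 21
  position: HBR
  device: XCT3000
  scout_98: frontal
  tibia66_detection: automatic
  has_duplicate_baseline: false
  muscle_sites: [MUSCLE_66]
  bone_sites: [TIBIA_04, TIBIA_38, TIBIA_66, TIBIA_98]
RSL:
  year: 2015
  n_subjects: 11
  duration_days: 60
  position: HDT
  device: XCT3000
  scout_98: sagittal
  tibia66_detection: automatic
  has_duplicate_baseline: true
  muscle_sites: [MUSCLE_38, MUSCLE_66]
  bone_sites: [TIBIA_04, TIBIA_38, TIBIA_66, TIBIA_98]
Valdoltra:
  year: 2007
  n_subjects: 10
  duration_days: 35
  position: HBR
  device: XCT2000
  scout_98: frontal
  tibia66_detection: automatic
  has_duplicate_baseline: true
  muscle_sites: []
  bone_sites: [TIBIA_04, TIBIA_38, TIBIA_98]
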
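# Illustrative category map: canonical (stemmed) keyword <TAB> track.
# Tracks: sensors/methods, biomedical, treatment, unassigned.
machin learn	sensors/methods
biomark	sensors/methods
electromyographi	sensors/methods
visual analog scale	sensors/methods
pain assess	sensors/methods
pain measur	sensors/methods
microdialysi	sensors/methods
magnetoencephalographi	sensors/methods
chronic pain	biomedical
low back pain	biomedical
neuropath pain	biomedical
acut pain	biomedical
cancer pain	biomedical
neck pain	biomedical
visceral pain	biomedical
dorsal root ganglion	biomedical
opioid	treatment
rehabilit	treatment
analges	treatment
surgeri	treatment
exercis	treatment
acupunctur	treatment
morphin	treatment
laser	treatment
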
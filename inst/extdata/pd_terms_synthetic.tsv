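# Synthetic starter PD term dictionary (reconstruction for tests and examples;
# not a published clinical resource). One term per line, optional TAB + tag.
# Tags: symptom, medication, advocacy, exercise, other.
parkinson	other
parkinsons	other
parkinsonism	other
parkinsonian	other
tremor	symptom
tremors	symptom
trembling	symptom
shaking	symptom
shaky	symptom
shakes	symptom
stiffness	symptom
stiff	symptom
rigidity	symptom
rigid	symptom
bradykinesia	symptom
slowness	symptom
dyskinesia	symptom
dystonia	symptom
freezing	symptom
shuffling	symptom
shuffle	symptom
balance	symptom
imbalance	symptom
unsteady	symptom
fall	symptom
falls	symptom
fell	symptom
falling	symptom
fallen	symptom
stumble	symptom
stumbled	symptom
tripped	symptom
dizzy	symptom
dizziness	symptom
lightheaded	symptom
fatigue	symptom
fatigued	symptom
tired	symptom
exhausted	symptom
insomnia	symptom
sleepless	symptom
slept	symptom
restless	symptom
sleep	symptom
sleeping	symptom
nightmares	symptom
drooling	symptom
swallowing	symptom
choking	symptom
constipation	symptom
handwriting	symptom
micrographia	symptom
cramp	symptom
cramps	symptom
cramping	symptom
pain	symptom
aching	symptom
achy	symptom
sore	symptom
dropped	symptom
dropping	symptom
numbness	symptom
tingling	symptom
weakness	symptom
anxiety	symptom
depression	symptom
apathy	symptom
hallucinations	symptom
memory	symptom
confusion	symptom
dementia	symptom
smell	symptom
anosmia	symptom
hoarse	symptom
mumbling	symptom
soft voice	symptom
voice	symptom
masked face	symptom
muscle pain	symptom
muscle spasms	symptom
restless legs	symptom
frozen gait	symptom
slow movement	symptom
falling down	symptom
fell down	symptom
lost balance	symptom
stooped posture	symptom
levodopa	medication
carbidopa	medication
sinemet	medication
rytary	medication
madopar	medication
ropinirole	medication
requip	medication
pramipexole	medication
mirapex	medication
rotigotine	medication
neupro	medication
amantadine	medication
gocovri	medication
rasagiline	medication
azilect	medication
selegiline	medication
safinamide	medication
xadago	medication
entacapone	medication
comtan	medication
stalevo	medication
opicapone	medication
ongentys	medication
trihexyphenidyl	medication
benztropine	medication
apomorphine	medication
apokyn	medication
duopa	medication
nuplazid	medication
pimavanserin	medication
dopamine	medication
agonist	medication
neurologist	medication
neurology	medication
movement disorder	other
movement disorder specialist	other
deep brain stimulation	medication
dbs surgery	medication
stimulator	medication
meds	medication
medication	medication
prescription	medication
dosage	medication
side effects	medication
wearing off	medication
off time	medication
on time	medication
physical therapy	medication
occupational therapy	medication
speech therapy	medication
big therapy	medication
lsvt	medication
michael j fox	advocacy
fox foundation	advocacy
team fox	advocacy
parkinson foundation	advocacy
parkinsons foundation	advocacy
moving day	advocacy
moving day walk	advocacy
davis phinney	advocacy
awareness month	advocacy
awareness walk	advocacy
tulip	advocacy
fundraiser	advocacy
support group	advocacy
caregiver	advocacy
care partner	advocacy
advocacy	advocacy
donate	advocacy
research study	advocacy
clinical trial	advocacy
exercise	exercise
exercising	exercise
workout	exercise
gym	exercise
yoga	exercise
tai chi	exercise
boxing	exercise
rock steady	exercise
rock steady boxing	exercise
cycling	exercise
spin class	exercise
treadmill	exercise
walking	exercise
walked	exercise
hiking	exercise
stretching	exercise
pilates	exercise
dance class	exercise
swimming	exercise
marathon	exercise
5k	exercise
strength training	exercise
physical activity	exercise
doctor	other
doctors	other
hospital	other
clinic	other
appointment	other
diagnosis	other
diagnosed	other
symptoms	other
symptom	other
disease	other
chronic	other
disability	other
wheelchair	other
walker	other
cane	other
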
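# Synthetic token -> cluster lookup table (stand-in for a large
# social-media-derived word clustering; built for tests and examples).
tremor	C01
tremors	C01
trembling	C01
shaking	C01
shaky	C01
shakes	C01
stiffness	C02
stiff	C02
rigidity	C02
rigid	C02
freezing	C02
slowness	C02
slow	C02
fall	C03
falls	C03
fell	C03
falling	C03
stumble	C03
stumbled	C03
tripped	C03
tumbling	C03
balance	C03
tired	C04
exhausted	C04
fatigue	C04
fatigued	C04
sleepy	C04
achy	C04
sore	C04
sleep	C05
sleeping	C05
slept	C05
insomnia	C05
night	C05
levodopa	C06
carbidopa	C06
sinemet	C06
ropinirole	C06
amantadine	C06
rasagiline	C06
meds	C06
medication	C06
prescription	C06
dosage	C06
neurologist	C07
neurology	C07
doctor	C07
clinic	C07
hospital	C07
appointment	C07
checkup	C07
surgery	C07
dbs	C07
parkinsons	C08
parkinson	C08
pd	C08
diagnosis	C08
diagnosed	C08
foundation	C09
fundraiser	C09
donate	C09
awareness	C09
advocacy	C09
volunteer	C09
walk	C10
walking	C10
walked	C10
hiked	C10
hiking	C10
gym	C11
workout	C11
exercise	C11
boxing	C11
yoga	C11
pilates	C11
treadmill	C11
cycling	C11
stretching	C11
swimming	C11
love	C12
loved	C12
wonderful	C12
amazing	C12
favorite	C12
adorable	C12
beautiful	C12
perfect	C12
great	C12
happy	C12
family	C13
friends	C13
friend	C13
sister	C13
brother	C13
cousin	C13
kids	C13
grandkids	C13
neighbors	C13
baby	C13
puppy	C13
dog	C13
dinner	C14
coffee	C14
pizza	C14
recipe	C14
lasagna	C14
brunch	C14
game	C15
match	C15
team	C15
football	C15
baseball	C15
concert	C16
recital	C16
song	C16
show	C16
novel	C16
book	C16
reading	C16
morning	C17
tonight	C17
today	C17
saturday	C17
sunday	C17
weekend	C17
week	C17
month	C17
support	C18
group	C18
caregiver	C18
community	C18
pain	C19
aching	C19
cramp	C19
cramping	C19
numbness	C19
tingling	C19
dizzy	C19
lightheaded	C19
memory	C20
handwriting	C20
voice	C20
worse	C21
worries	C21
worried	C21
scares	C21
nervous	C21
rough	C21
brutal	C21
traffic	C22
highway	C22
interstate	C22
drive	C22
weather	C23
sunset	C23
lake	C23
beach	C23
trail	C23
mountains	C23
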
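aaron
abigail
adam
agnes
alan
albert
alfred
alice
amos
andrew
angela
ann
anna
anne
anthony
arthur
austin
barbara
beatrice
benjamin
bernard
beryl
betty
brian
bridget
caleb
caroline
catherine
cecilia
charity
charles
christine
christopher
clara
clement
colin
collins
cornelius
cynthia
daniel
david
deborah
dennis
diana
dominic
donald
dorcas
doris
dorothy
duncan
edith
edward
edwin
elijah
elizabeth
emily
emma
enock
eric
esther
eunice
evans
evelyn
everlyne
ezekiel
faith
felix
florence
frances
francis
frederick
geoffrey
george
gilbert
gladys
gordon
grace
gregory
harriet
harrison
hellen
henry
hilda
hope
hosea
humphrey
ian
irene
isaac
jacob
james
jane
janet
japheth
jared
jason
jeremiah
jesse
joan
joel
john
jonathan
joseph
josephine
joshua
joyce
judith
julia
juliet
kenneth
kevin
laban
laura
lawrence
leah
leonard
lilian
linda
lillian
lois
lucas
lucy
luke
lydia
mabel
magdalene
margaret
mark
martha
martin
mary
matthew
maurice
mercy
michael
mildred
miriam
moses
nancy
naomi
nathan
nelson
nicholas
noah
norah
oliver
oscar
patricia
patrick
paul
pauline
penina
peter
philip
phoebe
priscilla
rachel
raymond
rebecca
reuben
rhoda
richard
risper
robert
rodgers
ronald
rose
rosemary
roy
ruth
salome
samson
samuel
sarah
selina
seth
silas
simon
solomon
stephen
susan
sylvia
tabitha
teresa
thomas
timothy
titus
tobias
tom
truphena
valentine
velma
victor
vincent
violet
vivian
walter
wilfred
william
winnie
zachary
zipporah
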